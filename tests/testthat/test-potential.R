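# all 24 permutations of 4 indices, enumerated recursively
combinat_perms <- function() {
  perm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  perm(1:4)
}

test_that("canonical keys are sorted and permutation-invariant", {
  expect_equal(canonical_key(c("H", "D", "C", "C")), "CCDH")
  expect_equal(canonical_key(c("A", "A", "A", "A")), "AAAA")
  perms <- matrix(c("W", "Y", "K", "G")[
    as.vector(t(do.call(rbind, combinat_perms())))], ncol = 4, byrow = TRUE)
  keys <- canonical_key(perms)
  expect_equal(unique(keys), "GKWY")
  expect_length(keys, 24)
  expect_error(canonical_key(c("A", "B", "C", "D")), "invalid")
})

test_that("quadruplet enumeration matches brute-force multiset counts", {
  expect_equal(enumerate_quadruplets(c("A", "B")),
               c("AAAA", "AAAB", "AABB", "ABBB", "BBBB"))
  # brute-force: all 4-tuples canonicalized, for small alphabets
  for (K in 2:5) {
    alpha <- LETTERS[seq_len(K)]
    tuples <- expand.grid(alpha, alpha, alpha, alpha,
                          stringsAsFactors = FALSE)
    brute <- sort(unique(apply(tuples, 1, function(r) {
      paste(sort(r), collapse = "")
    })))
    expect_equal(enumerate_quadruplets(alpha), brute)
    expect_length(brute, choose(K + 3, 4))
  }
  expect_length(enumerate_quadruplets(3), 15)
  expect_length(enumerate_quadruplets(), 8855)
})

test_that("observed frequencies recount simplices and sum to one", {
  obs <- observed_frequencies(fix_corpus)
  expect_equal(sum(obs$f), 1)
  # independent recount over the corpus
  recount <- table(unlist(lapply(fix_corpus, function(st) {
    tess <- tessellate(st, cutoff = 12)
    apply(tess$simplices, 1, function(s) {
      paste(sort(st$aa[s]), collapse = "")
    })
  })))
  expect_equal(setNames(obs$count, obs$key),
               setNames(as.integer(recount), names(recount))[obs$key])
  expect_equal(sum(obs$count), sum(recount))
})

test_that("residue composition pools corpus residues", {
  a <- residue_composition("AAC")
  expect_equal(unname(a["A"]), 2 / 3)
  expect_equal(unname(a["C"]), 1 / 3)
  expect_equal(sum(a), 1)
  # concatenation invariance
  expect_equal(residue_composition(c("AAC", "DD")),
               residue_composition("AACDD"))
  # a large uniform corpus is close to 0.05 per letter (binomial 3 sd)
  big <- generate_corpus(4, size_range = c(150, 200), seed = 9)
  a2 <- residue_composition(big)
  n_res <- sum(vapply(big, nrow, integer(1)))
  tol <- 3 * sqrt(0.05 * 0.95 / n_res)
  expect_true(all(abs(a2 - 0.05) < tol))
})

test_that("multinomial reference probabilities follow the formula", {
  a <- setNames(rep(0.05, 20), quadpot:::AA_ALPHABET)
  expect_equal(multinomial_reference("AAAA", a), 0.05^4)
  expect_equal(multinomial_reference("AACD", a), 12 * 0.05^4)
  # normalization for random compositions
  for (seed in 1:3) {
    w <- withr::with_seed(seed, stats::runif(20, 0.2, 1))
    comp <- setNames(w / sum(w), quadpot:::AA_ALPHABET)
    p <- multinomial_reference(enumerate_quadruplets(), comp)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("log-likelihood scores honor base and sign conventions", {
  expect_equal(log_likelihood_score(0.1, 0.1), 0)
  expect_equal(log_likelihood_score(0.1, 0.01, base = 10), 1)
  expect_equal(log_likelihood_score(0.1, 0.01, base = 10,
                                    sign = "neg_log_ratio"), -1)
  expect_equal(log_likelihood_score(0.2, 0.05, base = 2), 2)
  expect_error(log_likelihood_score(0.1, 0), "positive")
})

test_that("trained potentials cover all keys with conserved counts", {
  pot <- fix_potential
  expect_equal(nrow(pot), 8855)
  expect_true(all(is.finite(pot$s)))
  expect_equal(sum(pot$p), 1, tolerance = 1e-9)
  expect_equal(sum(pot$f), 1, tolerance = 1e-12)
  total_tets <- sum(vapply(fix_corpus, function(st) {
    nrow(tessellate(st, cutoff = 12)$simplices)
  }, numeric(1)))
  expect_equal(sum(pot$count), total_tets)
  expect_equal(attr(pot, "metadata")$total_tetrahedra, total_tets)
})

test_that("duplicating the corpus leaves f, p and s unchanged", {
  pot1 <- train_potential(fix_corpus[1:2])
  pot2 <- train_potential(c(fix_corpus[1:2], fix_corpus[1:2]))
  expect_equal(pot2$count, 2L * pot1$count)
  expect_equal(pot2$p, pot1$p)
  # with pseudocounts doubled counts shift f slightly; compare at pc = 0
  pot1r <- train_potential(fix_corpus[1:2], pseudocount = 0)
  pot2r <- train_potential(c(fix_corpus[1:2], fix_corpus[1:2]),
                           pseudocount = 0)
  expect_equal(pot2r$f, pot1r$f)
  expect_equal(pot2r$s, pot1r$s)
})

test_that("a single-tetrahedron corpus concentrates all frequency", {
  tess <- tessellate(toy_structure, cutoff = 12)
  obs <- observed_frequencies(list(list(tess = tess,
                                        sequence = toy_structure$aa)))
  expect_equal(nrow(obs), 1)
  expect_equal(obs$f, 1)
  expect_equal(obs$key, "ACDE")
})

test_that("potential tables round-trip losslessly through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_potential(fix_potential, path)
  back <- read_potential(path)
  expect_equal(back$key, fix_potential$key)
  expect_equal(back$count, fix_potential$count)
  expect_equal(back$f, fix_potential$f)
  expect_equal(back$p, fix_potential$p)
  expect_equal(back$s, fix_potential$s)
  expect_equal(attr(back, "metadata"), attr(fix_potential, "metadata"))
  expect_equal(attr(back, "composition"), attr(fix_potential, "composition"))
})

test_that("malformed potential tables fail with a line diagnosis", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\tcount\tf\tp\ts", "AAAA\t1\t0.5", "AAAC\t1\t0.5\t0.2\t0.1"),
             path)
  expect_error(read_potential(path), "line 1")
  writeLines(c("not a header"), path)
  expect_error(read_potential(path), "malformed")
})
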