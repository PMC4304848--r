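#' Canonical key of a residue quadruplet
#'
#' All permutations of the same four residues map to one key: the four
#' one-letter codes sorted in ascending alphabetical order (repeats allowed),
#' e.g. `(H, D, C, C)` becomes `"CCDH"`.
#'
#' @param residues Character vector of 4 one-letter codes, or a character
#'   matrix with 4 columns (one key per row).
#' @return Character vector of canonical keys.
#' @export
canonical_key <- function(residues) {
  if (is.matrix(residues)) {
    bad <- !(residues %in% AA_ALPHABET)
    if (any(bad)) abort("invalid amino acid letter in quadruplet")
    return(apply(residues, 1L, function(r) paste(sort(r), collapse = "")))
  }
  stopifnot(length(residues) == 4)
  if (!all(residues %in% AA_ALPHABET)) {
    abort("invalid amino acid letter in quadruplet")
  }
  paste(sort(residues), collapse = "")
}

#' Enumerate all distinct residue quadruplets
#'
#' Multisets of size `r` over a `K`-letter alphabet, in canonical (sorted)
#' form: `choose(K + r - 1, r)` keys.  For the standard 20-letter alphabet
#' and quadruplets (r of 4) this yields the 8,855 types over which the
#' four-body potential is defined.
#'
#' @param alphabet Character vector of letters (default the 20 amino acids),
#'   or an integer `K` meaning the first `K` amino acid letters.
#' @param r Multiset size (default 4).
#' @return Character vector of canonical keys, lexicographically sorted.
#' @examples
#' length(enumerate_quadruplets())  # 8855
#' enumerate_quadruplets(2)         # AAAA AAAC AACC ACCC CCCC
#' @export
enumerate_quadruplets <- function(alphabet = AA_ALPHABET, r = 4) {
  if (is.numeric(alphabet)) alphabet <- AA_ALPHABET[seq_len(alphabet)]
  K <- length(alphabet)
  stopifnot(K >= 1, r >= 1)
  idx <- utils::combn(K + r - 1, r)          # strictly increasing r-tuples
  idx <- idx - (seq_len(r) - 1L)             # back to non-decreasing multisets
  apply(idx, 2L, function(i) paste(alphabet[i], collapse = ""))
}

# Canonical keys of every retained simplex of one tessellation.
simplex_keys <- function(tess, sequence) {
  if (nrow(tess$simplices) == 0) return(character())
  aa <- matrix(sequence[as.vector(tess$simplices)],
               nrow = nrow(tess$simplices))
  canonical_key(aa)
}

# Resolve a sequence argument: a quadpot_structure, or a character vector
# aligned with (and optionally named by) the tessellation positions.
resolve_sequence <- function(x, tess) {
  if (inherits(x, "quadpot_structure")) {
    seqv <- x$aa[match(tess$positions, x$seq_number)]
  } else if (!is.null(names(x))) {
    seqv <- unname(x[as.character(tess$positions)])
  } else {
    if (length(x) != nrow(tess$coords)) {
      abort("sequence length does not match the number of vertices")
    }
    seqv <- as.character(x)
  }
  if (anyNA(seqv)) abort("sequence does not cover all tessellation vertices")
  seqv
}

#' Observed quadruplet frequencies in a corpus
#'
#' Counts, over all retained tetrahedra of every tessellation in the corpus,
#' how often each canonical quadruplet occurs, and converts counts to
#' relative frequencies `f` (proportion of all tetrahedra).
#'
#' @param corpus A list of `list(tess = , sequence = )` pairs (or of
#'   `quadpot_structure` objects, which are tessellated with `cutoff`).
#' @param cutoff Edge cutoff used when corpus elements are structures.
#' @return A tibble `key`, `count`, `f` over the observed keys;
#'   `sum(f) == 1`.
#' @export
observed_frequencies <- function(corpus, cutoff = 12) {
  corpus <- normalize_corpus(corpus, cutoff)
  if (length(corpus) == 0) abort("empty corpus")
  keys <- unlist(purrr::map(corpus, function(el) {
    simplex_keys(el$tess, el$sequence)
  }))
  if (length(keys) == 0) abort("corpus contains no retained tetrahedra")
  tab <- table(keys)
  tibble(key = names(tab), count = as.integer(tab),
         f = as.integer(tab) / length(keys))
}

normalize_corpus <- function(corpus, cutoff) {
  if (inherits(corpus, "quadpot_structure")) corpus <- list(corpus)
  purrr::map(corpus, function(el) {
    if (inherits(el, "quadpot_structure")) {
      tess <- tessellate(el, cutoff = cutoff)
      list(tess = tess, sequence = resolve_sequence(el, tess))
    } else {
      list(tess = el$tess, sequence = resolve_sequence(el$sequence, el$tess))
    }
  })
}

#' Residue composition of a corpus
#'
#' Proportion `a_n` of all residues (pooled over every chain of the corpus)
#' that are of each of the 20 types.
#'
#' @param sequences Character vector(s) of one-letter codes, a list of such
#'   vectors, or structures/corpus elements.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
residue_composition <- function(sequences) {
  if (inherits(sequences, "quadpot_structure")) sequences <- list(sequences)
  pooled <- unlist(purrr::map(sequences, function(el) {
    if (inherits(el, "quadpot_structure")) return(el$aa)
    if (is.list(el)) return(as.character(el$sequence))
    as.character(el)
  }))
  pooled <- unlist(strsplit(pooled, "", fixed = TRUE))
  if (length(pooled) == 0) abort("no residues supplied")
  if (!all(pooled %in% AA_ALPHABET)) abort("invalid amino acid letter")
  tab <- table(factor(pooled, levels = AA_ALPHABET))
  as.vector(tab / sum(tab)) |> setNames(AA_ALPHABET)
}

#' Multinomial reference probability of a quadruplet
#'
#' The chance rate of occurrence of a quadruplet under the multinomial
#' model: `p = 4! / prod(t_n!) * prod(a_n^t_n)`, where `t_n` counts repeats
#' of residue type `n` within the quadruplet and `a_n` is the corpus
#' composition.
#'
#' @param keys Character vector of canonical keys.
#' @param a Named composition vector over the 20 residues (sums to 1).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
multinomial_reference <- function(keys, a) {
  stopifnot(abs(sum(a) - 1) < 1e-6)
  vapply(keys, function(k) {
    letters4 <- strsplit(k, "", fixed = TRUE)[[1]]
    t_n <- table(letters4)
    factorial(4) / prod(factorial(as.integer(t_n))) *
      prod(a[names(t_n)]^as.integer(t_n))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Log-likelihood score of a quadruplet
#'
#' Inverted-Boltzmann log-ratio of observed to expected frequency.  With the
#' default convention `sign = "log_ratio"`, overrepresented (favorable)
#' quadruplets score positive: `s = log(f/p)`.  The alternative
#' `"neg_log_ratio"` gives `s = -log(f/p)`.
#'
#' @param f Observed relative frequencies.
#' @param p Reference probabilities (all `> 0`).
#' @param base Logarithm base (default 10).
#' @param sign `"log_ratio"` or `"neg_log_ratio"`.
#' @return Numeric scores; `-Inf`/`Inf` can only arise when `f = 0`, which
#'   [train_potential()] prevents via its pseudo-count policy.
#' @export
log_likelihood_score <- function(f, p, base = 10,
                                 sign = c("log_ratio", "neg_log_ratio")) {
  sign <- match.arg(sign)
  if (any(p <= 0)) abort("reference probability must be positive")
  s <- log(f / p, base = base)
  if (sign == "neg_log_ratio") -s else s
}

#' Train a four-body statistical potential
#'
#' Derives the full quadruplet score table from a corpus of tessellated
#' structures: observed tetrahedron frequencies (after edge filtering),
#' multinomial reference probabilities from the corpus residue composition,
#' and log-likelihood scores.  Every one of the `choose(23, 4) = 8855`
#' canonical keys receives a record.  An additive pseudo-count (default 1) is
#' applied to all counts before computing `f`, so unobserved quadruplets get
#' finite scores.
#'
#' @param corpus List of structures or `list(tess=, sequence=)` pairs.
#' @param cutoff Edge-length cutoff in Angstrom (default 12).
#' @param log_base Logarithm base for scores (default 10).
#' @param sign Score sign convention, see [log_likelihood_score()].
#' @param pseudocount Additive count applied to every key (default 1; 0
#'   disables, leaving unobserved keys at `-Inf` under `"log_ratio"`).
#' @return A `quadpot_potential`: tibble `key`, `count`, `f`, `p`, `s` with
#'   composition and metadata attributes.
#' @examples
#' corpus <- generate_corpus(3, size_range = c(40, 60), seed = 1)
#' pot <- train_potential(corpus)
#' pot
#' @export
train_potential <- function(corpus, cutoff = 12, log_base = 10,
                            sign = c("log_ratio", "neg_log_ratio"),
                            pseudocount = 1) {
  sign <- match.arg(sign)
  corpus <- normalize_corpus(corpus, cutoff)
  obs <- observed_frequencies(corpus)
  a <- residue_composition(corpus)
  keys <- enumerate_quadruplets()
  count <- integer(length(keys))
  count[match(obs$key, keys)] <- obs$count
  adj <- count + pseudocount
  f <- adj / sum(adj)
  p <- multinomial_reference(keys, a)
  s <- log_likelihood_score(f, p, base = log_base, sign = sign)
  new_potential(
    tibble(key = keys, count = count, f = f, p = p, s = s),
    composition = a,
    metadata = list(corpus_size = length(corpus),
                    total_tetrahedra = sum(count),
                    cutoff = cutoff, log_base = log_base, sign = sign,
                    pseudocount = pseudocount))
}

new_potential <- function(df, composition, metadata) {
  structure(df, composition = composition, metadata = metadata,
            class = c("quadpot_potential", class(df)))
}

#' @export
print.quadpot_potential <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("<quadpot_potential> ", nrow(x), " quadruplet types\n", sep = "")
  cat("  corpus: ", md$corpus_size, " chain(s), ", md$total_tetrahedra,
      " tetrahedra, cutoff ", md$cutoff, " A\n", sep = "")
  cat("  score: log base ", md$log_base, ", sign ", md$sign,
      ", pseudocount ", md$pseudocount, "\n", sep = "")
  NextMethod()
}

#' Look up quadruplet scores
#'
#' @param potential A `quadpot_potential`.
#' @param keys Canonical keys.
#' @return Numeric scores.
#' @export
lookup_scores <- function(potential, keys) {
  idx <- match(keys, potential$key)
  if (anyNA(idx)) {
    abort(paste0("quadruplet(s) absent from potential: ",
                 paste(unique(keys[is.na(idx)]), collapse = ", ")))
  }
  potential$s[idx]
}

#' Write a potential table to TSV
#'
#' The format is a plain TSV with `#`-prefixed metadata header lines
#' (corpus_size, total_tetrahedra, cutoff, log_base, sign, pseudocount, and
#' the 20 composition values) followed by `key count f p s` rows.
#' `read_potential(write_potential(p, path))` is lossless.
#'
#' @param potential A `quadpot_potential`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_potential <- function(potential, path) {
  md <- attr(potential, "metadata")
  a <- attr(potential, "composition")
  hdr <- c(
    sprintf("# corpus_size\t%d", md$corpus_size),
    sprintf("# total_tetrahedra\t%d", md$total_tetrahedra),
    sprintf("# cutoff\t%.17g", md$cutoff),
    sprintf("# log_base\t%.17g", md$log_base),
    sprintf("# sign\t%s", md$sign),
    sprintf("# pseudocount\t%.17g", md$pseudocount),
    sprintf("# composition\t%s",
            paste(sprintf("%s=%.17g", names(a), a), collapse = ",")),
    "key\tcount\tf\tp\ts")
  rows <- sprintf("%s\t%d\t%.17g\t%.17g\t%.17g", potential$key,
                  potential$count, potential$f, potential$p, potential$s)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a potential table from TSV
#'
#' @param path Path written by [write_potential()] (or any table with the
#'   same schema; 8,855 rows are expected for the full alphabet).
#' @return A `quadpot_potential`.
#' @export
read_potential <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  md <- list(corpus_size = NA_integer_, total_tetrahedra = NA_integer_,
             cutoff = NA_real_, log_base = 10, sign = "log_ratio",
             pseudocount = NA_real_)
  a <- setNames(rep(NA_real_, 20), AA_ALPHABET)
  for (ml in meta_lines) {
    parts <- strsplit(sub("^#\\s*", "", ml), "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) next
    key <- parts[1]; val <- parts[2]
    if (key == "composition") {
      kv <- strsplit(strsplit(val, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      for (p0 in kv) a[p0[1]] <- as.numeric(p0[2])
    } else if (key == "sign") {
      md$sign <- val
    } else if (key %in% c("corpus_size", "total_tetrahedra")) {
      md[[key]] <- as.integer(val)
    } else {
      md[[key]] <- as.numeric(val)
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2 || body[1] != "key\tcount\tf\tp\ts") {
    abort("malformed potential table: missing 'key\\tcount\\tf\\tp\\ts' header")
  }
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5)) {
    abort(paste0("malformed potential table at data line ",
                 which(nf != 5)[1], ": expected 5 tab-separated fields"))
  }
  m <- do.call(rbind, fields)
  df <- tibble(key = m[, 1], count = as.integer(m[, 2]),
               f = as.numeric(m[, 3]), p = as.numeric(m[, 4]),
               s = as.numeric(m[, 5]))
  if (anyNA(df$f) || anyNA(df$p) || anyNA(df$s)) {
    abort("malformed potential table: non-numeric f/p/s values")
  }
  new_potential(df, composition = a, metadata = md)
}
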