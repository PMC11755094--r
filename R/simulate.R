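#' Simulate a set of homologous sequences
#'
#' Generates a uniform-random ancestral DNA sequence and `n_seqs` descendants
#' mutated independently: per-site substitution to one of the three other
#' bases with probability `sub_rate`, and at each position an indel event
#' with probability `indel_rate` (insertion or deletion with equal chance)
#' whose length is geometric with success probability `indel_geom_p` (mean
#' `1/indel_geom_p`). The defaults emulate homolog sets in the 82-100%
#' pairwise identity range at desk scale. Deterministic for a given seed.
#'
#' @param ancestor_length Length of the ancestral sequence (> 0).
#' @param n_seqs Number of descendant sequences.
#' @param sub_rate Per-site substitution probability in `[0, 1]`.
#' @param indel_rate Per-site indel event probability in `[0, 1]`.
#' @param indel_geom_p Geometric length parameter in `(0, 1]`.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return Named character vector of `n_seqs` sequences, with the ancestor
#'   attached as attribute `"ancestor"` and per-sequence provenance in the
#'   names (`seqK_subS_indI`).
#' @examples
#' seqs <- simulate_homologs(60, 3, sub_rate = 0.05, indel_rate = 0.02, seed = 1)
#' @export
simulate_homologs <- function(ancestor_length, n_seqs = 5L, sub_rate = 0.05,
                              indel_rate = 0.02, indel_geom_p = 0.5, seed) {
  if (ancestor_length < 1L) stop("ancestor_length must be positive", call. = FALSE)
  if (n_seqs < 1L) stop("n_seqs must be positive", call. = FALSE)
  if (sub_rate < 0 || sub_rate > 1 || indel_rate < 0 || indel_rate > 1) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (indel_geom_p <= 0 || indel_geom_p > 1) {
    stop("indel_geom_p must be in (0, 1]", call. = FALSE)
  }
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, ancestor_length, replace = TRUE)
  out <- character(n_seqs)
  nm <- character(n_seqs)
  for (k in seq_len(n_seqs)) {
    x <- anc
    nsub <- 0L
    sub_at <- which(runif(length(x)) < sub_rate)
    if (length(sub_at)) {
      for (p in sub_at) x[p] <- sample(setdiff(bases, x[p]), 1L)
      nsub <- length(sub_at)
    }
    nind <- 0L
    ind_at <- which(runif(length(x)) < indel_rate)
    # apply right-to-left so earlier positions stay valid
    for (p in rev(ind_at)) {
      len <- rgeom(1L, indel_geom_p) + 1L
      nind <- nind + 1L
      if (runif(1L) < 0.5) {  # insertion after position p
        ins <- sample(bases, len, replace = TRUE)
        x <- append(x, ins, after = p)
      } else {                # deletion starting at position p
        drop <- p:min(p + len - 1L, length(x))
        if (length(drop) < length(x)) x <- x[-drop]
      }
    }
    out[k] <- paste(x, collapse = "")
    nm[k] <- sprintf("seq%d_sub%d_ind%d", k, nsub, nind)
  }
  names(out) <- nm
  attr(out, "ancestor") <- paste(anc, collapse = "")
  out
}
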