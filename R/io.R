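#' Read sequences from a FASTA file
#'
#' Wrapped or unwrapped FASTA is accepted. Sequences are uppercased;
#' duplicate record names are rejected. With `rna_to_dna = TRUE`, `U` is
#' mapped to `T`.
#'
#' @param path FASTA file.
#' @param rna_to_dna Map `U` to `T` (default off).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, rna_to_dna = FALSE) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' has no records", call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names in '", path, "'", call. = FALSE)
  }
  if (rna_to_dna) seqs <- chartr("U", "T", seqs)
  seqs
}

#' Write sequences (or MSA rows) as FASTA
#'
#' Output is wrapped at 80 columns. For a `poa_msa`, the gapped rows are
#' written (aligned multi-FASTA).
#'
#' @param x Named character vector, or a `poa_msa`.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "poa_msa")) x <- x$rows
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Write a POA graph as GFA v1
#'
#' A deliberately naive dialect keeping node ids stable: one single-character
#' segment per labeled node (S lines), links with `0M` overlap (L lines), and
#' one path per threaded sequence (P lines). The virtual terminals are
#' omitted.
#'
#' @param g A `poa_graph`.
#' @param path Output file.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (v in real_nodes(g)) {
    writeLines(sprintf("S\t%d\t%s", v, g$labels[v]), con)
  }
  for (v in real_nodes(g)) {
    for (w in g$succ[[v]]) {
      if (w == TAU) next
      writeLines(sprintf("L\t%d\t+\t%d\t+\t0M", v, w), con)
    }
  }
  for (s in seq_along(g$seq_paths)) {
    p <- g$seq_paths[[s]]
    writeLines(sprintf("P\t%s\t%s\t*", g$seq_names[s],
                       paste0(p, "+", collapse = ",")), con)
  }
  invisible(path)
}

#' Read a GFA v1 file back into a POA graph
#'
#' Restores topology, labels and sequence paths from the dialect written by
#' [write_gfa()]. MSA column classes are not representable in GFA, so every
#' node is restored into its own class; the graph is fully usable for further
#' alignment and extension.
#'
#' @param path GFA file.
#' @return A `poa_graph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  types <- vapply(parts, `[[`, character(1), 1L)
  sl <- parts[types == "S"]
  ids <- vapply(sl, function(p) as.integer(p[2]), integer(1))
  labs <- vapply(sl, `[[`, character(1), 3L)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  labels <- character(length(ids))
  labels[remap[ids]] <- labs
  ll <- parts[types == "L"]
  edges <- if (length(ll)) {
    cbind(vapply(ll, function(p) remap[as.integer(p[2])], integer(1)),
          vapply(ll, function(p) remap[as.integer(p[4])], integer(1)))
  } else NULL
  pl <- parts[types == "P"]
  paths <- NULL
  pnames <- NULL
  if (length(pl)) {
    pnames <- vapply(pl, `[[`, character(1), 2L)
    paths <- lapply(pl, function(p) {
      remap[as.integer(sub("[+-]$", "", strsplit(p[3], ",", fixed = TRUE)[[1]]))]
    })
  }
  poa_graph_from_edges(labels, edges, paths = paths, seq_names = pnames)
}

#' Write a POA graph in DOT format
#'
#' Nodes show their label; edges are labeled with the number of sequences
#' using them.
#'
#' @param g A `poa_graph`.
#' @param path Output file.
#' @export
write_dot <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("digraph poa {", con)
  writeLines("  rankdir=LR;", con)
  writeLines(sprintf("  n%d [label=\"%s\", shape=circle];", NU, "nu"), con)
  writeLines(sprintf("  n%d [label=\"%s\", shape=circle];", TAU, "tau"), con)
  for (v in real_nodes(g)) {
    writeLines(sprintf("  n%d [label=\"%s\"];", v, g$labels[v]), con)
  }
  for (v in seq_len(n_nodes(g))) {
    for (k in seq_along(g$succ[[v]])) {
      w <- g$succ[[v]][k]
      nseq <- length(g$edge_seqs[[v]][[k]])
      writeLines(sprintf("  n%d -> n%d [label=\"%d\"];", v, w, nseq), con)
    }
  }
  writeLines("}", con)
  invisible(path)
}

#' Write per-sequence alignment statistics as TSV
#'
#' @param stats Data frame as produced by [build_msa()] (`$stats`).
#' @param path Output file.
#' @export
write_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
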