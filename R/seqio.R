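#' Read a FASTA file
#'
#' Sequences are uppercased and returned in file order as a named character
#' vector. When \code{alignment = TRUE} (the default) all sequences must
#' have equal length.
#'
#' @param path path to a FASTA file.
#' @param alignment require equal sequence lengths.
#' @return a named character vector of sequences.
#' @export
read_fasta <- function(path, alignment = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  nms <- vapply(strsplit(names(ss), "[ \t]+"), `[`, "", 1L)
  if (any(!nzchar(nms))) stop("FASTA record with empty name in ", path)
  if (anyDuplicated(nms))
    stop("duplicate FASTA names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(seqs) <- nms
  if (alignment && length(unique(nchar(seqs))) != 1L)
    stop("sequences have unequal lengths but an alignment is required")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 60L)
  invisible(path)
}

aln_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

matrix_aln <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  if (ncol(m) == 0L) out <- setNames(rep("", nrow(m)), rownames(m))
  out
}

#' Remove gap and ambiguous columns from an alignment
#'
#' A column is kept iff every residue in it belongs to the (uppercase)
#' alphabet; anything else -- gaps, '.', 'X', 'B', 'Z', 'J', 'U', 'O',
#' '*', '?', lowercase -- drops the column.
#'
#' @param aln named character vector of equal-length sequences.
#' @param alphabet allowed residues (default the 20 canonical amino acids).
#' @return a list with \code{alignment} (trimmed sequences) and \code{kept}
#'   (1-based indices of the retained columns of the input).
#' @export
trim_alignment <- function(aln, alphabet = PAML_RESIDUES) {
  if (length(unique(nchar(aln))) > 1L) stop("alignment is not rectangular")
  L <- nchar(aln[[1]])
  if (L == 0L) return(list(alignment = aln, kept = integer(0)))
  m <- aln_matrix(aln)
  keep <- apply(m, 2L, function(col) all(col %in% alphabet))
  kept <- which(keep)
  list(alignment = matrix_aln(m[, kept, drop = FALSE]), kept = kept)
}

#' Construct and validate an ancestral-sequence record
#'
#' The unit consumed by identification and expectation: a labeled guide
#' tree with branch lengths, one relative replacement rate per alignment
#' column, and one sequence per tree node (tips and internal ancestors).
#'
#' @param tree a \code{phylo} object with all nodes named.
#' @param site_rates positive numeric vector, one rate per column.
#' @param sequences named character vector covering exactly the tree's
#'   node names, all of one length equal to \code{length(site_rates)}.
#' @return an object of class \code{ancestral_record}.
#' @export
ancestral_record <- function(tree, site_rates, sequences) {
  nm <- node_names(tree)
  if (any(!nzchar(nm)))
    stop("ancestral record requires every tree node to be named")
  missing <- setdiff(nm, names(sequences))
  if (length(missing))
    stop("missing sequence for node(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(sequences), nm)
  if (length(extra))
    stop("sequence name(s) not in tree: ", paste(extra, collapse = ", "))
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences have unequal lengths")
  if (length(site_rates) != lens)
    stop("got ", length(site_rates), " site rates for sequences of length ",
         lens)
  if (any(!is.finite(site_rates)) || any(site_rates <= 0))
    stop("site rates must all be positive")
  structure(list(tree = tree, site_rates = as.numeric(site_rates),
                 sequences = sequences[nm]),
            class = "ancestral_record")
}

#' @export
print.ancestral_record <- function(x, ...) {
  cat("Ancestral sequence record:", length(x$tree$tip.label), "tips,",
      x$tree$Nnode, "internal nodes,", length(x$site_rates), "sites\n")
  invisible(x)
}

#' Read an ancestral-sequence record file
#'
#' Tab-delimited layout: line 1 the Newick guide tree (branch lengths,
#' labeled internal nodes); line 3 the tab-separated per-site replacement
#' rates; lines 5 and below one \code{name<TAB>sequence} row per tree node.
#' Lines 2 and 4 are ignored. A missing or blank rate line defaults every
#' rate to 1 with a warning.
#'
#' @param path path to a record file.
#' @return an \code{ancestral_record}.
#' @export
read_ancestral_record <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L || !nzchar(trimws(lines[1])))
    stop("line 1: missing guide tree")
  tree <- tryCatch(parse_newick(lines[1]),
                   error = function(e) stop("line 1: ", conditionMessage(e)))
  seq_lines <- if (length(lines) >= 5L) lines[5:length(lines)] else character(0)
  seq_lines <- seq_lines[nzchar(trimws(seq_lines))]
  if (!length(seq_lines)) stop("line 5: no sequence rows found")
  parts <- strsplit(seq_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("line ", 4L + bad[1], ": expected name<TAB>sequence")
  seqs <- setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
  seqs <- toupper(seqs)
  L <- nchar(seqs[[1]])
  rate_line <- if (length(lines) >= 3L) lines[3] else ""
  if (!nzchar(trimws(rate_line))) {
    warning("line 3: no site rates found; defaulting all rates to 1")
    rates <- rep(1, L)
  } else {
    rates <- suppressWarnings(
      as.numeric(strsplit(trimws(rate_line), "[\t ]+")[[1]]))
    if (anyNA(rates)) stop("line 3: non-numeric site rate")
  }
  tryCatch(ancestral_record(tree, rates, seqs),
           error = function(e) stop("invalid record ", path, ": ",
                                    conditionMessage(e)))
}

#' Write an ancestral-sequence record file
#'
#' @param record an \code{ancestral_record}.
#' @param path output path.
#' @export
write_ancestral_record <- function(record, path) {
  rates <- sprintf("%.17g", record$site_rates)
  lines <- c(write_newick(record$tree), "",
             paste(rates, collapse = "\t"), "",
             paste(names(record$sequences), record$sequences, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
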