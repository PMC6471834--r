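#' Amino-acid replacements along one branch
#'
#' @param record an \code{ancestral_record}.
#' @param branch child-node name identifying the branch.
#' @return a data frame with columns \code{site} (1-based column),
#'   \code{from}, \code{to}, one row per site where the parent and child
#'   sequences differ.
#' @export
branch_replacements <- function(record, branch) {
  br <- branches(record$tree)
  row <- match(branch, br$child)
  if (is.na(row)) stop("unknown branch (child node): ", branch)
  p <- strsplit(record$sequences[[br$parent[row]]], "")[[1]]
  c_ <- strsplit(record$sequences[[branch]], "")[[1]]
  idx <- which(p != c_)
  data.frame(site = idx, from = p[idx], to = c_[idx],
             stringsAsFactors = FALSE)
}

#' Identify parallel and convergent replacements
#'
#' For every comparable branch pair and every site, an event is emitted iff
#' both branches changed state at that site and both arrived at the same
#' descendant residue; the event is parallel (P) when the two ancestral
#' residues are equal and convergent (C) when they differ. At most one
#' event can occur per pair and site.
#'
#' @param record an \code{ancestral_record}.
#' @return a list with \code{counts} (data frame: \code{first},
#'   \code{second}, \code{parallel}, \code{convergent}; one row per
#'   comparable pair, zeros included) and \code{events} (data frame:
#'   \code{category}, \code{site}, \code{first}, \code{second}, \code{a1},
#'   \code{d1}, \code{a2}, \code{d2}; sorted by pair then site). Residues
#'   \code{a1 -> d1} are the replacement on the \code{first} branch.
#' @export
identify_events <- function(record) {
  tree <- record$tree
  pairs <- comparable_pairs(tree)
  m <- aln_matrix(record$sequences)
  br <- branches(tree)
  # per branch: ancestral row, descendant row, changed-site mask
  anc <- m[br$parent, , drop = FALSE]
  des <- m[br$child, , drop = FALSE]
  rownames(anc) <- rownames(des) <- br$child
  chg <- anc != des

  np <- nrow(pairs)
  cnt_p <- integer(np)
  cnt_c <- integer(np)
  ev <- vector("list", np)
  for (i in seq_len(np)) {
    b1 <- pairs$first[i]; b2 <- pairs$second[i]
    idx <- which(chg[b1, ] & chg[b2, ] & des[b1, ] == des[b2, ])
    if (length(idx)) {
      a1 <- anc[b1, idx]; a2 <- anc[b2, idx]
      cat_ <- ifelse(a1 == a2, "P", "C")
      cnt_p[i] <- sum(cat_ == "P")
      cnt_c[i] <- sum(cat_ == "C")
      ev[[i]] <- data.frame(category = cat_, site = idx,
                            first = b1, second = b2,
                            a1 = a1, d1 = des[b1, idx],
                            a2 = a2, d2 = des[b2, idx],
                            stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  events <- do.call(rbind, ev)
  if (is.null(events))
    events <- data.frame(category = character(0), site = integer(0),
                         first = character(0), second = character(0),
                         a1 = character(0), d1 = character(0),
                         a2 = character(0), d2 = character(0),
                         stringsAsFactors = FALSE)
  counts <- data.frame(first = pairs$first, second = pairs$second,
                       parallel = cnt_p, convergent = cnt_c,
                       stringsAsFactors = FALSE)
  list(counts = counts, events = events)
}

#' Write per-pair replacement counts to TSV
#'
#' Columns: \code{pair} (rendered "A-B" in canonical order),
#' \code{parallel}, \code{convergent}.
#'
#' @param counts the counts data frame from \code{identify_events}.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  out <- data.frame(pair = pair_key(counts$first, counts$second),
                    parallel = counts$parallel,
                    convergent = counts$convergent)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write replacement-event details to TSV
#'
#' Columns: \code{category}, \code{position}, \code{pair}, \code{r1},
#' \code{r2}, replacements rendered as \code{"K->R"}.
#'
#' @param events the events data frame from \code{identify_events}.
#' @param path output path.
#' @export
write_details_tsv <- function(events, path) {
  n <- nrow(events)
  out <- data.frame(category = events$category,
                    position = events$site,
                    pair = if (n) pair_key(events$first, events$second)
                           else character(0),
                    r1 = if (n) paste0(events$a1, "->", events$d1)
                         else character(0),
                    r2 = if (n) paste0(events$a2, "->", events$d2)
                         else character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
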