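#' Residues of the standard amino-acid alphabet, PAML order
#'
#' The 20 canonical amino acids in the residue order used by PAML-format
#' substitution-model files (A R N D C Q E G H I L K M F P S T W Y V).
#' All alphabet-dependent operations default to this order.
#'
#' @export
PAML_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# name of every node, indexed by ape node number (tips first, then internals)
node_names <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl[is.na(nl)] <- ""
  c(tree$tip.label, nl)
}

root_node <- function(tree) {
  # the unique node that never appears as a child
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

# integer parent lookup: parent_of[node] (NA for root)
parent_map <- function(tree) {
  pm <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  pm[tree$edge[, 2]] <- tree$edge[, 1]
  pm
}

node_number <- function(tree, name) {
  nm <- node_names(tree)
  idx <- match(name, nm)
  if (anyNA(idx)) stop("unknown node name(s): ",
                       paste(name[is.na(idx)], collapse = ", "))
  idx
}

#' Parse a Newick tree
#'
#' Reads a single rooted Newick statement into an \code{ape} \code{phylo}
#' object, preserving topology, node names, branch lengths and
#' multifurcations. Branch lengths absent from the input are recorded as
#' \code{NA}.
#'
#' @param text a Newick string terminated by \code{";"}.
#' @return an object of class \code{phylo}.
#' @examples
#' tr <- parse_newick("((A:1,B:2)X:1,C:3)R;")
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("empty Newick input")
  s <- trimws(text)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of input")
  if (!endsWith(s, ";"))
    stop("malformed Newick: missing terminating ';' at position ", nchar(s))
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = s)),
                   error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick: unparseable statement")
  if (!is.null(tree$edge.length))
    tree$edge.length[!is.finite(tree$edge.length)] <- NA_real_
  nm <- node_names(tree)
  dup <- unique(nm[nzchar(nm) & duplicated(nm)])
  if (length(dup))
    stop("duplicate node name(s): ", paste(dup, collapse = ", "))
  tree
}

#' Write a tree as a Newick string
#'
#' Children are emitted in stored order; branch lengths with up to 9
#' significant digits; \code{NA} lengths are omitted.
#'
#' @param tree a \code{phylo} object.
#' @return a Newick string ending in \code{";"}.
#' @export
write_newick <- function(tree) {
  nm <- node_names(tree)
  pm <- parent_map(tree)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- rep(NA_real_, length(nm))
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  fmt <- function(node) {
    lab <- nm[node]
    sub <- if (node > ntip) {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, fmt, ""), collapse = ","), ")")
    } else ""
    len <- if (!is.na(elen[node]) && !is.na(pm[node]))
      sprintf(":%.9g", elen[node]) else ""
    paste0(sub, lab, len)
  }
  paste0(fmt(root_node(tree)), ";")
}

#' Label unnamed internal nodes
#'
#' Assigns deterministic names \code{"N<k>"} to unnamed internal nodes in
#' preorder (root first), with \code{k} starting at 1 and skipping names
#' already present anywhere in the tree. Idempotent.
#'
#' @param tree a \code{phylo} object with unique tip names.
#' @return the tree with every internal node named.
#' @export
label_unnamed_internals <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- tree$node.label
  if (is.null(nl)) nl <- rep("", tree$Nnode)
  nl[is.na(nl)] <- ""
  taken <- c(tree$tip.label, nl[nzchar(nl)])
  cl <- ape::reorder.phylo(tree, "cladewise")
  pre <- unique(cl$edge[, 1])          # internal nodes in preorder
  k <- 1L
  for (node in pre) {
    i <- node - ntip
    if (!nzchar(nl[i])) {
      repeat {
        cand <- paste0("N", k)
        k <- k + 1L
        if (!cand %in% taken) break
      }
      nl[i] <- cand
      taken <- c(taken, cand)
    }
  }
  tree$node.label <- nl
  tree
}

#' Is one node an ancestor of another?
#'
#' @param tree a \code{phylo} object with named nodes.
#' @param u,v node names.
#' @return \code{TRUE} iff \code{u} lies on the path from the root to
#'   \code{v}, excluding \code{v} itself.
#' @export
is_ancestor <- function(tree, u, v) {
  un <- node_number(tree, u)
  vn <- node_number(tree, v)
  pm <- parent_map(tree)
  node <- pm[vn]
  while (!is.na(node)) {
    if (node == un) return(TRUE)
    node <- pm[node]
  }
  FALSE
}

#' Enumerate branches of a tree
#'
#' A branch is the edge above a non-root node and is identified by its
#' child node's name.
#'
#' @param tree a \code{phylo} object with named nodes.
#' @return a data frame with columns \code{child}, \code{parent},
#'   \code{length} (one row per non-root node).
#' @export
branches <- function(tree) {
  nm <- node_names(tree)
  len <- if (is.null(tree$edge.length)) rep(NA_real_, nrow(tree$edge))
         else tree$edge.length
  data.frame(child = nm[tree$edge[, 2]], parent = nm[tree$edge[, 1]],
             length = len, stringsAsFactors = FALSE)
}

#' Branch pairs eligible for parallelism/convergence comparison
#'
#' Returns every unordered pair of branches that (i) are not siblings
#' (different parent nodes) and (ii) do not share an evolutionary path
#' (neither branch's child node is an ancestor of the other's). Only such
#' pairs can evidence independent evolution.
#'
#' @param tree a \code{phylo} object with named nodes.
#' @return a data frame with columns \code{first}, \code{second} (branch
#'   child-node names, \code{first < second} lexicographically), sorted by
#'   (\code{first}, \code{second}).
#' @export
comparable_pairs <- function(tree) {
  nm <- node_names(tree)
  pm <- parent_map(tree)
  nn <- length(nm)
  rt <- root_node(tree)
  nonroot <- setdiff(seq_len(nn), rt)
  # ancestor sets by climbing to the root
  anc <- vector("list", nn)
  for (v in nonroot) {
    path <- integer(0)
    node <- pm[v]
    while (!is.na(node)) {
      path <- c(path, node)
      node <- pm[node]
    }
    anc[[v]] <- path
  }
  out_first <- character(0)
  out_second <- character(0)
  k <- length(nonroot)
  if (k >= 2L) {
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) {
      u <- nonroot[a]; v <- nonroot[b]
      if (pm[u] == pm[v]) next                    # siblings share a node
      if (u %in% anc[[v]] || v %in% anc[[u]]) next # shared path
      pr <- sort(c(nm[u], nm[v]))
      out_first <- c(out_first, pr[1])
      out_second <- c(out_second, pr[2])
    }
  }
  out <- data.frame(first = out_first, second = out_second,
                    stringsAsFactors = FALSE)
  out[order(out$first, out$second), , drop = FALSE]
}

# canonical "A-B" rendering used by every output file
pair_key <- function(first, second) paste(first, second, sep = "-")
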