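# Diagnostic-state distances and UPGMA clustering.

#' Pairwise distance between two diagnostic state vectors
#'
#' Mean per-position mismatch over scored positions. Under the `"partial"`
#' ambiguity policy a position contributes `1 - |intersection| / |union|` of
#' the two observed character sets (so `R` vs `A` costs 1/2); under
#' `"strict"` any set inequality costs 1. With `gap_policy = "missing"`
#' positions where either vector shows a plain gap are dropped from the
#' denominator; the default `"deletion"` scores the gap as a fifth character
#' state.
#'
#' @param a,b state vectors of equal length.
#' @param ambiguity `"partial"` or `"strict"`.
#' @param gap_policy `"deletion"` (default) or `"missing"`.
#' @return non-negative real.
#' @examples
#' sc <- load_scheme()
#' state_distance(reference_vector(sc, "A"), reference_vector(sc, "B"),
#'                ambiguity = "strict")  # 6/14
#' @export
state_distance <- function(a, b, ambiguity = c("partial", "strict"),
                           gap_policy = c("deletion", "missing")) {
  ambiguity <- match.arg(ambiguity)
  gap_policy <- match.arg(gap_policy)
  if (length(a) != length(b)) {
    stop("state vectors must have equal length", call. = FALSE)
  }
  sa <- lapply(a, char_set)
  sb <- lapply(b, char_set)
  scored <- rep(TRUE, length(a))
  if (gap_policy == "missing") {
    scored <- !(vapply(sa, identical, logical(1), "-") |
                  vapply(sb, identical, logical(1), "-"))
  }
  if (!any(scored)) {
    stop("undefined distance: zero scorable positions", call. = FALSE)
  }
  contrib <- vapply(which(scored), function(i) {
    if (ambiguity == "strict") {
      as.numeric(!setequal(sa[[i]], sb[[i]]))
    } else {
      1 - length(intersect(sa[[i]], sb[[i]])) / length(union(sa[[i]], sb[[i]]))
    }
  }, numeric(1))
  mean(contrib)
}

#' Distance matrix over the rows of a state matrix
#'
#' @param tab data frame in the fixture layout.
#' @param scheme a `diagnostic_scheme`.
#' @param ... passed on to [state_distance()].
#' @return symmetric labelled matrix with zero diagonal.
#' @export
state_distance_matrix <- function(tab, scheme = load_scheme(), ...) {
  n <- nrow(tab)
  vecs <- lapply(seq_len(n), function(i) {
    as.character(unlist(tab[i, as.character(scheme$positions)]))
  })
  m <- matrix(0, n, n, dimnames = list(tab$sample_id, tab$sample_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- state_distance(vecs[[i]], vecs[[j]], ...)
    }
  }
  m
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L) {
    stop("distance matrix must be square with at least two taxa", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distance matrix error: entries must be finite and non-negative",
         call. = FALSE)
  }
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop("distance matrix error: must be symmetric with zero diagonal",
         call. = FALSE)
  }
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  }
  invisible(d)
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the size-weighted arithmetic mean of its
#' parts' distances, and each internal node sits at half its merge distance,
#' so the result is ultrametric. Ties are broken deterministically by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by the smallest leaf it contains).
#'
#' @param d symmetric labelled distance matrix (zero diagonal).
#' @return an object of class `upgma_tree`: a nested list of nodes, each
#'   with `height` (0 at the leaves), `label` (leaves) or `children`.
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A","B"), c("A","B")))
#' to_newick(upgma(d))  # "(A:0.2,B:0.2);"
#' @export
upgma <- function(d) {
  d <- validate_distance_matrix(d)
  labels <- rownames(d)
  n <- length(labels)
  nodes <- lapply(labels, function(l) {
    structure(list(height = 0, label = l), class = "upgma_node")
  })
  sizes <- rep(1L, n)
  key <- labels  # smallest contained leaf label per active cluster
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        pair_key <- sort(c(key[i], key[j]))
        cand <- list(d = d[i, j], key = pair_key, i = i, j = j)
        if (is.null(best) || cand$d < best$d - 1e-15 ||
            (abs(cand$d - best$d) <= 1e-15 &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    child_i <- nodes[[i]]; child_j <- nodes[[j]]
    merged <- structure(list(height = h, children = list(child_i, child_j)),
                        class = "upgma_node")
    # size-weighted mean distances to the new cluster, stored in slot i
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    key[i] <- min(key[i], key[j])
    active <- setdiff(active, j)
  }
  structure(list(root = nodes[[active]], labels = labels),
            class = "upgma_tree")
}

tree_leaves <- function(node) {
  if (!is.null(node$label)) return(node$label)
  unlist(lapply(node$children, tree_leaves))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), x$root$height))
  invisible(x)
}

#' Serialize an UPGMA tree to Newick
#'
#' Branch lengths are parent height minus child height; children are ordered
#' by the smallest leaf label they contain, so the string is a canonical
#' form of the tree.
#'
#' @param t an `upgma_tree`.
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(t) {
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  rec <- function(node, parent_height) {
    bl <- fmt(parent_height - node$height)
    if (!is.null(node$label)) return(paste0(node$label, ":", bl))
    kids <- node$children[order(vapply(node$children,
                                       function(k) min(tree_leaves(k)),
                                       character(1)))]
    inner <- paste(vapply(kids, rec, character(1),
                          parent_height = node$height), collapse = ",")
    paste0("(", inner, "):", bl)
  }
  root <- t$root
  if (!is.null(root$label)) return(paste0(root$label, ";"))
  kids <- root$children[order(vapply(root$children,
                                     function(k) min(tree_leaves(k)),
                                     character(1)))]
  inner <- paste(vapply(kids, rec, character(1),
                        parent_height = root$height), collapse = ",")
  paste0("(", inner, ");")
}

#' Cophenetic distances implied by an UPGMA tree
#'
#' @param t an `upgma_tree`.
#' @return labelled symmetric matrix with `d(i, j)` equal to twice the
#'   height of the lowest common ancestor of `i` and `j`.
#' @export
cophenetic_upgma <- function(t) {
  labs <- sort(t$labels)
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  rec <- function(node) {
    if (!is.null(node$label)) return(node$label)
    parts <- lapply(node$children, rec)
    for (a in seq_along(parts)[-length(parts)]) {
      for (b in (a + 1):length(parts)) {
        m[parts[[a]], parts[[b]]] <<- 2 * node$height
        m[parts[[b]], parts[[a]]] <<- 2 * node$height
      }
    }
    unlist(parts)
  }
  rec(t$root)
  m
}

all_heights <- function(node) {
  if (!is.null(node$label)) return(numeric(0))
  c(node$height, unlist(lapply(node$children, all_heights)))
}

clusters_at <- function(node, h) {
  if (!is.null(node$label)) return(list(node$label))
  if (node$height <= h) return(list(tree_leaves(node)))
  unlist(lapply(node$children, clusters_at, h = h), recursive = FALSE)
}

#' Minimal pure horizontal cut of a labelled UPGMA tree
#'
#' Scans every horizontal cut of the tree and returns the smallest number of
#' clusters such that no cluster mixes leaves from different groups. A tree
#' in which one group is exclusive under the root yields 2.
#'
#' @param t an `upgma_tree`.
#' @param groups named character vector mapping every leaf label to a group.
#' @return integer number of clusters.
#' @export
group_partition_check <- function(t, groups) {
  leaves <- t$labels
  if (!all(leaves %in% names(groups))) {
    stop("every leaf must be assigned a group", call. = FALSE)
  }
  hs <- sort(unique(c(-1, all_heights(t$root))))
  best <- length(leaves)
  for (h in hs) {
    cl <- clusters_at(t$root, h)
    pure <- all(vapply(cl, function(x) {
      length(unique(groups[x])) == 1L
    }, logical(1)))
    if (pure) best <- min(best, length(cl))
  }
  best
}
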