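#' Allele-sharing (1 - IBS) distance between samples
#'
#' For dosage-coded genotypes, two samples share `2 - |g1 - g2|` alleles at
#' a co-called site, so the distance is
#' `d = 1 - shared / (2 * co-called sites)`, which is `0` for identical
#' vectors and `1` for opposite homozygotes throughout. Pairs with fewer
#' than `min_co_called` co-called sites are flagged unreliable; a pair with
#' zero co-called sites is an error unless `permissive = TRUE` (the pair is
#' then flagged and its distance set to `NA`).
#'
#' @param gm a `genotype_matrix` (needs at least 2 samples).
#' @param min_co_called reliability threshold on co-called site counts.
#' @param permissive tolerate zero-overlap pairs.
#' @return an object of class `ibs_dist`: list with `d` (symmetric distance
#'   matrix, zero diagonal), `n_co_called` (pairwise co-called counts) and
#'   `unreliable` (logical matrix).
#' @export
allele_sharing_distance <- function(gm, min_co_called = 0,
                                    permissive = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  ns <- ncol(g)
  if (ns < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- colnames(g)
  d <- matrix(0, ns, ns, dimnames = list(labels, labels))
  nc <- matrix(0L, ns, ns, dimnames = list(labels, labels))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      n <- sum(ok)
      nc[i, j] <- nc[j, i] <- n
      if (n == 0) {
        if (!permissive)
          stop("samples ", labels[i], " and ", labels[j],
               " share no co-called sites", call. = FALSE)
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      dij <- sum(abs(g[ok, i] - g[ok, j])) / (2 * n)
      d[i, j] <- d[j, i] <- dij
    }
  }
  diag(nc) <- colSums(!is.na(g))
  structure(list(d = d, n_co_called = nc,
                 unreliable = nc < min_co_called & !diag(TRUE, ns)),
            class = "ibs_dist")
}

#' Average inter-group distances
#'
#' Collapses a per-sample distance matrix to group (species) level by
#' averaging all between-group entries, for a group-level tree.
#'
#' @param dm an `ibs_dist`, `dist` or square matrix.
#' @param groups group label per sample (in matrix column order).
#' @return square group-level distance matrix, zero diagonal.
#' @export
group_mean_distance <- function(dm, groups) {
  d <- as_dist_matrix(dm)
  stopifnot(length(groups) == ncol(d))
  gl <- unique(groups)
  out <- matrix(0, length(gl), length(gl), dimnames = list(gl, gl))
  for (a in seq_along(gl)) {
    for (b in seq_along(gl)) {
      if (a == b) next
      out[a, b] <- mean(d[groups == gl[a], groups == gl[b]])
    }
  }
  out
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "ibs_dist")) return(dm$d)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  as.matrix(dm)
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration: at each step the pair
#' minimising the Q-criterion
#' `Q(i,j) = (r - 2) d(i,j) - R(i) - R(j)` (with `R` the row sums over the
#' `r` active nodes) is joined, branch lengths follow the usual
#' `v_i = d(i,j)/2 + (R_i - R_j) / (2(r - 2))` formula, and distances to
#' the new node are `(d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q break
#' toward the lexicographically smallest node pair (in node creation
#' order), making the output deterministic. Negative branch lengths are
#' reported as computed unless `clamp_negative = TRUE`.
#'
#' @param dm an `ibs_dist`, `dist` or symmetric square matrix with at least
#'   3 taxa.
#' @param clamp_negative clamp negative branch lengths to zero for display.
#' @return an unrooted [ape] `phylo` tree.
#' @export
neighbor_joining <- function(dm, clamp_negative = FALSE) {
  d <- as_dist_matrix(dm)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) ||
      any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries a growing newick fragment
  frag <- vapply(labels, quote_newick_label, character(1))
  active <- seq_len(n)            # creation-order ids of active nodes
  dd <- d
  fmt <- function(x) {
    if (clamp_negative) x <- max(x, 0)
    sprintf("%.12g", x)
  }
  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(dd)
    q_best <- Inf
    pair <- c(NA, NA)
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        q <- (r - 2) * dd[i, j] - R[i] - R[j]
        if (q < q_best - 1e-12) {
          q_best <- q
          pair <- c(i, j)
        }
        # ties resolved by the loop order: lexicographically smallest
        # (i, j) in node creation order wins because strict improvement is
        # required to replace the incumbent
      }
    }
    i <- pair[1]; j <- pair[2]
    vi <- dd[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dd[i, j] - vi
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":",
                       fmt(vj), ")")
    duk <- (dd[i, ] + dd[j, ] - dd[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    frag <- c(frag[keep], new_frag)
    active <- c(active[keep], max(active) + 1L)
  }
  # final three-way join: closed-form three-point branch lengths
  va <- (dd[1, 2] + dd[1, 3] - dd[2, 3]) / 2
  vb <- (dd[1, 2] + dd[2, 3] - dd[1, 3]) / 2
  vc <- (dd[1, 3] + dd[2, 3] - dd[1, 2]) / 2
  newick <- paste0("(", frag[1], ":", fmt(va), ",", frag[2], ":", fmt(vb),
                   ",", frag[3], ":", fmt(vc), ");")
  ape::read.tree(text = newick)
}

quote_newick_label <- function(x) {
  if (grepl("[ ,;:()\\[\\]']", x))
    paste0("'", gsub("'", "''", x), "'") else x
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; branch
#' lengths survive a round trip to at least 10 significant digits.
#'
#' @param tree an ape `phylo` object.
#' @param path file path.
#' @return the path (write) or a `phylo` (read).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
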