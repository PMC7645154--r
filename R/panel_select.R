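## Three-stage even-spacing selection of a marker panel.
##
## Stage I walks 1 kb bins and keeps the two edge-nearest SNPs per bin;
## Stage II merges 10 bins, caps dense 10 kb bins at 10 markers by
## nearest-to-uniform-target matching and tops sparse bins back up to 7 from
## their own dropped pool; Stage III scans each chromosome for adjacent-
## marker gaps over 2 kb and back-fills them with dropped SNPs nearest the
## gap midpoints. All ties break toward the lower coordinate; bins are
## 0-based half-open and partial bins at chromosome ends are real bins.

bin_of <- function(pos, width) (pos - 1L) %/% as.integer(width)

#' Pick k sites nearest to equispaced targets
#'
#' Defines k target positions `t_i = start + (i - 0.5) * L / k` over the
#' 0-based half-open interval `[start, end)` and greedily matches each
#' target, in order, to its nearest unassigned site (ties to the lower
#' coordinate).
#'
#' @param pos integer vector of site positions (1-based).
#' @param start,end interval bounds, 0-based half-open.
#' @param k number of sites to pick; must not exceed `length(pos)`.
#' @return indices into `pos` of the picked sites, in ascending position
#'   order.
#' @export
uniform_pick <- function(pos, start, end, k) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (length(pos) < k)
    stop("fewer sites than requested picks", call. = FALSE)
  x <- pos - 1                       # 0-based coordinates
  L <- end - start
  targets <- start + (seq_len(k) - 0.5) * L / k
  taken <- rep(FALSE, length(pos))
  picked <- integer(0)
  for (t in targets) {
    d <- abs(x - t)
    d[taken] <- Inf
    # nearest unassigned site; which.min returns the first (lowest pos,
    # since pos is sorted) on ties
    i <- which.min(d)
    taken[i] <- TRUE
    picked <- c(picked, i)
  }
  sort(picked)
}

new_selection_state <- function(candidates, genome, config) {
  index <- genome_index(genome)
  len <- chrom_length(index, candidates$chrom)
  if (any(candidates$pos < 1 | candidates$pos > len))
    stop("candidate site outside genome bounds", call. = FALSE)
  st <- candidates[order(candidates$chrom, candidates$pos,
                         if (!is.null(candidates$alt)) candidates$alt), ,
                   drop = FALSE]
  st <- st[!duplicated(st[, c("chrom", "pos")]), , drop = FALSE]
  st$state <- "dropped"
  st$stage <- NA_character_
  rownames(st) <- NULL
  attr(st, "index") <- index
  st
}

#' Stage I: edge-nearest pick per small bin
#'
#' Splits each chromosome into `small_bin`-sized bins. A bin with one SNP
#' keeps it; a bin with two or more keeps the SNP nearest its left boundary
#' and the SNP nearest its right boundary (for sorted positions, the first
#' and last in the bin); the remainder moves to the dropped pool.
#'
#' @param candidates data.frame with `chrom`, `pos` (duplicated coordinates
#'   are collapsed to the first record).
#' @param genome DNAStringSet or [genome_index()].
#' @param config a [select_config()].
#' @return the selection state: `candidates` ordered by position with
#'   `state` (`selected`/`dropped`) and `stage` columns; genome index kept
#'   as attribute `index`.
#' @export
stage1_edge_pick <- function(candidates, genome, config = select_config()) {
  st <- new_selection_state(candidates, genome, config)
  bin <- paste(st$chrom, bin_of(st$pos, config$small_bin))
  for (b in unique(bin)) {
    i <- which(bin == b)            # ascending pos within bin
    pick <- if (length(i) == 1L) i else c(i[1L], i[length(i)])
    st$state[pick] <- "selected"
    st$stage[pick] <- "stage1"
  }
  st
}

#' Stage II: density adjustment on merged bins
#'
#' Merges `merge_factor` adjacent small bins. Bins holding more than
#' `bin_target` selected SNPs are thinned to exactly `bin_target` by
#' [uniform_pick()]; bins in the `[bin_floor, bin_target]` band are left
#' alone; bins below `bin_floor` re-promote their own dropped SNPs
#' (nearest-to-uniform-target first) until the floor is reached or the
#' bin's dropped pool is exhausted.
#'
#' @param state output of [stage1_edge_pick()].
#' @param config a [select_config()].
#' @return updated selection state.
#' @export
stage2_density_adjust <- function(state, config = select_config()) {
  index <- attr(state, "index")
  if (is.null(index)) stop("selection state lacks its genome index",
                           call. = FALSE)
  width <- config$small_bin * config$merge_factor
  bin_id <- bin_of(state$pos, width)
  bin <- paste(state$chrom, bin_id)
  for (b in unique(bin)) {
    i <- which(bin == b)
    sel <- i[state$state[i] == "selected"]
    s <- length(sel)
    start <- bin_id[i[1L]] * width
    end <- min(start + width, chrom_length(index, state$chrom[i[1L]]))
    if (s > config$bin_target) {
      keep_local <- uniform_pick(state$pos[sel], start, end,
                                 config$bin_target)
      demote <- sel[-keep_local]
      state$state[demote] <- "dropped"
      state$stage[demote] <- NA_character_
    } else if (s < config$bin_floor) {
      pool <- i[state$state[i] == "dropped"]
      need <- config$bin_floor - s
      if (length(pool) > 0 && need > 0) {
        k <- config$bin_floor
        targets <- start + (seq_len(k) - 0.5) * (end - start) / k
        d <- vapply(state$pos[pool] - 1, function(x)
          min(abs(x - targets)), numeric(1))
        ord <- pool[order(d, state$pos[pool])]
        promote <- ord[seq_len(min(need, length(ord)))]
        state$state[promote] <- "selected"
        state$stage[promote] <- "stage2"
      }
    }
  }
  state
}

#' Stage III: gap back-filling
#'
#' Scans each chromosome left to right over the selected positions
#' (chromosome start and end act as virtual boundaries). While an
#' adjacent gap exceeds `max_gap` and an unused dropped SNP lies strictly
#' inside it, the dropped SNP nearest the gap midpoint is promoted and the
#' two half-gaps are re-examined (innermost first, left half first). On
#' return, any residual gap over `max_gap` contains no unused dropped SNP.
#'
#' @param state output of [stage2_density_adjust()].
#' @param config a [select_config()].
#' @return updated selection state.
#' @export
stage3_gap_fill <- function(state, config = select_config()) {
  index <- attr(state, "index")
  if (is.null(index)) stop("selection state lacks its genome index",
                           call. = FALSE)
  for (chr in unique(state$chrom)) {
    ci <- which(state$chrom == chr)
    len <- chrom_length(index, chr)
    sel_pos <- state$pos[ci[state$state[ci] == "selected"]]
    avail <- ci[state$state[ci] == "dropped"]     # indices into state
    bounds <- c(0L, sort(sel_pos), len)
    # LIFO stack of gaps; push right half then left half so the left half
    # is examined first
    stack <- Map(c, head(bounds, -1L), tail(bounds, -1L))
    while (length(stack) > 0) {
      g <- stack[[1L]]
      stack <- stack[-1L]
      if (g[2L] - g[1L] <= config$max_gap) next
      inside <- avail[state$pos[avail] > g[1L] & state$pos[avail] < g[2L]]
      if (length(inside) == 0) next
      mid <- (g[1L] + g[2L]) / 2
      d <- abs(state$pos[inside] - mid)
      pick <- inside[order(d, state$pos[inside])][1L]
      state$state[pick] <- "selected"
      state$stage[pick] <- "stage3"
      avail <- setdiff(avail, pick)
      p <- state$pos[pick]
      stack <- c(list(c(g[1L], p), c(p, g[2L])), stack)
    }
  }
  state
}

#' Run the full three-stage selection
#'
#' @param candidates candidate data.frame (`chrom`, `pos`, plus any columns
#'   to carry through, e.g. alleles and flanks).
#' @param genome DNAStringSet or [genome_index()].
#' @param config a [select_config()].
#' @return list with `panel` (selected sites, class `snp_panel`, sorted and
#'   deduplicated, `stage` column recording the selecting stage) and
#'   `audit` (every candidate with its final `state` and `stage`).
#' @export
select_panel <- function(candidates, genome, config = select_config()) {
  st <- stage1_edge_pick(candidates, genome, config)
  st <- stage2_density_adjust(st, config)
  st <- stage3_gap_fill(st, config)
  panel <- st[st$state == "selected", setdiff(names(st), "state"),
              drop = FALSE]
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  attr(panel, "index") <- attr(st, "index")
  list(panel = panel, audit = st)
}

#' Add trait-related and control markers to a panel
#'
#' Fixed markers join the panel unconditionally (never displacing selected
#' markers); a fixed marker already on the panel has its provenance upgraded
#' to `trait`/`control`. Duplicates within the fixed lists collapse to one
#' entry. Markers outside the genome are an error.
#'
#' @param panel a `snp_panel` (needs attribute `index`, as produced by
#'   [select_panel()], or pass `genome`).
#' @param trait_snps,control_snps data.frames with `chrom`, `pos`, `ref`,
#'   `alt` (either may be `NULL`).
#' @param genome optional DNAStringSet or [genome_index()] overriding the
#'   panel's stored index.
#' @param probe_config optional [probe_filter_config()]: fixed markers whose
#'   flanks are available are checked against the probe rules, but a failure
#'   only warns — fixed markers are never removed.
#' @return the augmented `snp_panel`, sorted by chromosome and position.
#' @export
add_fixed_markers <- function(panel, trait_snps = NULL, control_snps = NULL,
                              genome = NULL, probe_config = NULL) {
  index <- if (!is.null(genome)) genome_index(genome) else
    attr(panel, "index")
  if (is.null(index)) stop("no genome index available", call. = FALSE)
  add_one <- function(panel, fixed, label) {
    if (is.null(fixed) || nrow(fixed) == 0) return(panel)
    fixed <- fixed[!duplicated(fixed[, c("chrom", "pos")]), , drop = FALSE]
    if (!is.null(probe_config) &&
        all(c("flank_left", "flank_right") %in% names(fixed))) {
      for (i in which(!is.na(fixed$flank_left) &
                        !is.na(fixed$flank_right))) {
        chk <- check_probe(fixed[i, , drop = FALSE], config = probe_config)
        if (!chk$pass)
          warning(label, " marker ", marker_id(fixed[i, ]),
                  " fails probe rules (", paste(chk$reasons,
                                                collapse = ", "),
                  ") but is kept", call. = FALSE)
      }
    }
    len <- chrom_length(index, fixed$chrom)
    if (any(fixed$pos < 1 | fixed$pos > len))
      stop(label, " marker outside genome bounds", call. = FALSE)
    hit <- match(marker_id(fixed), marker_id(panel))
    panel$stage[hit[!is.na(hit)]] <- label
    novel <- fixed[is.na(hit), , drop = FALSE]
    if (nrow(novel) > 0) {
      novel$stage <- label
      for (col in setdiff(names(panel), names(novel))) novel[[col]] <- NA
      panel <- rbind(panel, novel[, names(panel)])
    }
    panel
  }
  idx_attr <- index
  panel <- add_one(panel, trait_snps, "trait")
  panel <- add_one(panel, control_snps, "control")
  panel <- panel[order(panel$chrom, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  attr(panel, "index") <- idx_attr
  panel
}
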