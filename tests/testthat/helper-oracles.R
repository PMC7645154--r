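# Independent reference implementations used as oracles. These are written
# as plain, literal transcriptions of the rules (loops and recursion, no
# shared code with the package) so that agreement is meaningful.

# ---- probe screen oracles: exhaustive character scans ----

oracle_gc <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  hits <- 0
  for (ch in chars) if (ch == "G" || ch == "C") hits <- hits + 1
  hits / length(chars)
}

oracle_max_run <- function(s, subset) {
  chars <- strsplit(toupper(s), "")[[1]]
  best <- 0L
  cur <- 0L
  for (ch in chars) {
    if (ch %in% subset) {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else {
      cur <- 0L
    }
  }
  best
}

# ---- three-stage selection oracle (single chromosome) ----

oracle_uniform_targets <- function(start, end, k) {
  start + (seq_len(k) - 0.5) * (end - start) / k
}

# greedy nearest-site-to-target matching, ties to the lower coordinate
oracle_uniform_pick <- function(pos, start, end, k) {
  targets <- oracle_uniform_targets(start, end, k)
  avail <- sort(pos)
  chosen <- integer(0)
  for (t in targets) {
    d <- abs((avail - 1) - t)
    best <- avail[order(d, avail)][1]
    chosen <- c(chosen, best)
    avail <- setdiff(avail, best)
  }
  sort(chosen)
}

oracle_select_chrom <- function(pos, chrom_len, cfg) {
  pos <- sort(unique(pos))
  sb <- cfg$small_bin
  selected <- integer(0)
  dropped <- integer(0)
  stage <- character(0)
  # Stage I: per small bin keep the edge-nearest pair (min and max position)
  for (b in 0:((chrom_len - 1) %/% sb)) {
    inbin <- pos[pos > b * sb & pos <= b * sb + sb]
    if (length(inbin) == 0) next
    keep <- if (length(inbin) == 1) inbin else c(min(inbin), max(inbin))
    selected <- c(selected, keep)
    stage[as.character(keep)] <- "stage1"
    dropped <- c(dropped, setdiff(inbin, keep))
  }
  # Stage II: merged bins
  W <- sb * cfg$merge_factor
  for (mb in 0:((chrom_len - 1) %/% W)) {
    start <- mb * W
    end <- min(start + W, chrom_len)
    sel_in <- selected[selected > start & selected <= start + W]
    s <- length(sel_in)
    if (s > cfg$bin_target) {
      keep <- oracle_uniform_pick(sel_in, start, end, cfg$bin_target)
      demote <- setdiff(sel_in, keep)
      selected <- setdiff(selected, demote)
      stage <- stage[!names(stage) %in% as.character(demote)]
      dropped <- c(dropped, demote)
    } else if (s < cfg$bin_floor) {
      pool <- dropped[dropped > start & dropped <= start + W]
      if (length(pool) > 0) {
        targets <- oracle_uniform_targets(start, end, cfg$bin_floor)
        dist_to_target <- sapply(pool, function(p)
          min(abs((p - 1) - targets)))
        ordered <- pool[order(dist_to_target, pool)]
        promote <- ordered[seq_len(min(cfg$bin_floor - s, length(ordered)))]
        selected <- c(selected, promote)
        stage[as.character(promote)] <- "stage2"
        dropped <- setdiff(dropped, promote)
      }
    }
  }
  # Stage III: recursive midpoint gap filling; gaps partition the
  # chromosome so processing order cannot change the outcome
  env <- new.env()
  env$selected <- selected
  env$dropped <- dropped
  env$stage <- stage
  fill <- function(left, right) {
    if (right - left <= cfg$max_gap) return(invisible())
    inside <- env$dropped[env$dropped > left & env$dropped < right]
    if (length(inside) == 0) return(invisible())
    mid <- (left + right) / 2
    p <- inside[order(abs(inside - mid), inside)][1]
    env$selected <- c(env$selected, p)
    env$stage[as.character(p)] <- "stage3"
    env$dropped <- setdiff(env$dropped, p)
    fill(left, p)
    fill(p, right)
  }
  bounds <- c(0, sort(env$selected), chrom_len)
  for (i in seq_len(length(bounds) - 1)) fill(bounds[i], bounds[i + 1])
  sel <- sort(env$selected)
  list(selected = sel, stage = unname(env$stage[as.character(sel)]))
}

oracle_select <- function(candidates, index, cfg) {
  out <- lapply(index$chrom, function(ch) {
    p <- candidates$pos[candidates$chrom == ch]
    if (length(p) == 0)
      return(list(selected = integer(0), stage = character(0)))
    oracle_select_chrom(p, index$length[index$chrom == ch], cfg)
  })
  names(out) <- index$chrom
  out
}

# ---- site-filter brute-force re-check (per-rule, row by row) ----

oracle_site_keep <- function(row, cfg) {
  if (!is.null(row$site_quality) && !is.na(row$site_quality) &&
      row$site_quality < cfg$min_site_quality) return(FALSE)
  if (!is.null(row$mapping_quality) && !is.na(row$mapping_quality) &&
      row$mapping_quality < cfg$min_mapping_quality) return(FALSE)
  if (!is.null(row$coverage) && !is.na(row$coverage) &&
      row$coverage < cfg$min_coverage) return(FALSE)
  if (is.na(row$maf) || row$maf < cfg$min_maf) return(FALSE)
  if (row$n_missing > cfg$max_missing_primary) return(FALSE)
  if (row$mac < cfg$min_minor_allele_count) return(FALSE)
  if (row$n_missing > cfg$max_missing_secondary) return(FALSE)
  if (row$n_alleles > cfg$max_alleles) return(FALSE)
  TRUE
}
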