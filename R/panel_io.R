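#' Extract probe flanks for SNP sites
#'
#' Attaches the `flank` bases immediately 5' (`flank_left`) and 3'
#' (`flank_right`) of each site from the genome sequence. Sites closer than
#' `flank` bases to a chromosome end are marked `excluded` with reason
#' `insufficient_flank`; all others become (or stay) `candidate`.
#'
#' @param sites data.frame with `chrom` and `pos` columns.
#' @param genome a DNAStringSet covering all sites.
#' @param flank flank length in bases (default 35).
#' @return `sites` with columns `flank_left`, `flank_right`, `state` and
#'   `exclude_reason` added or updated.
#' @export
extract_flanks <- function(sites, genome, flank = 35) {
  stopifnot(is.data.frame(sites), inherits(genome, "DNAStringSet"))
  index <- genome_index(genome)
  len <- chrom_length(index, sites$chrom)
  if (any(sites$pos < 1 | sites$pos > len))
    stop("site position outside chromosome bounds", call. = FALSE)
  seqs <- as.character(genome)
  n <- nrow(sites)
  sites$flank_left <- NA_character_
  sites$flank_right <- NA_character_
  if (is.null(sites$state)) sites$state <- "candidate"
  if (is.null(sites$exclude_reason)) sites$exclude_reason <- NA_character_
  ok <- sites$pos - flank >= 1 & sites$pos + flank <= len
  for (i in which(ok)) {
    s <- seqs[[sites$chrom[i]]]
    sites$flank_left[i] <- substr(s, sites$pos[i] - flank, sites$pos[i] - 1L)
    sites$flank_right[i] <- substr(s, sites$pos[i] + 1L, sites$pos[i] + flank)
  }
  sites$state[!ok] <- "excluded"
  sites$exclude_reason[!ok] <- "insufficient_flank"
  sites
}

#' Write / read a marker panel
#'
#' Panels are TSVs with one row per marker: `marker_id`, `chrom`, `pos`,
#' `probe_context` in the bracket notation of array submission sheets
#' (`left_flank[ref/alt]right_flank`), and `stage` (which selection stage
#' placed the marker on the panel). Reading a panel with duplicate
#' coordinates is an error.
#'
#' @param panel data.frame with `chrom`, `pos`, `ref`, `alt`, `flank_left`,
#'   `flank_right`, `stage` columns (flanks may be `NA`).
#' @param path file path.
#' @return the path (write) or the panel (read).
#' @export
write_panel <- function(panel, path) {
  stopifnot(is.data.frame(panel))
  ctx <- probe_context(panel)
  out <- data.frame(marker_id = marker_id(panel), chrom = panel$chrom,
                    pos = panel$pos, probe_context = ctx,
                    stage = if (is.null(panel$stage)) NA else panel$stage,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  m <- regmatches(df$probe_context,
                  regexec("^([ACGTN]*)\\[([ACGTN]+)/([ACGTN,]+)\\]([ACGTN]*)$",
                          df$probe_context))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad))
    stop("unparseable probe context at row ", which(bad)[1], call. = FALSE)
  panel <- data.frame(
    chrom = as.character(df$chrom), pos = as.integer(df$pos),
    ref = vapply(m, `[`, character(1), 3),
    alt = vapply(m, `[`, character(1), 4),
    flank_left = vapply(m, `[`, character(1), 2),
    flank_right = vapply(m, `[`, character(1), 5),
    stage = df$stage, stringsAsFactors = FALSE)
  panel$flank_left[panel$flank_left == ""] <- NA_character_
  panel$flank_right[panel$flank_right == ""] <- NA_character_
  if (anyDuplicated(panel[, c("chrom", "pos")]))
    stop("duplicate marker coordinates in panel file", call. = FALSE)
  panel <- panel[order(panel$chrom, panel$pos), ]
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Probe context string
#'
#' `left_flank[ref/alt]right_flank`; for 35-base flanks and single-base
#' alleles this is 75 characters.
#'
#' @param sites data.frame with `ref`, `alt` and optional flank columns.
#' @return character vector.
#' @export
probe_context <- function(sites) {
  fl <- if (is.null(sites$flank_left)) rep(NA_character_, nrow(sites)) else
    sites$flank_left
  fr <- if (is.null(sites$flank_right)) rep(NA_character_, nrow(sites)) else
    sites$flank_right
  fl[is.na(fl)] <- ""
  fr[is.na(fr)] <- ""
  paste0(fl, "[", sites$ref, "/", sites$alt, "]", fr)
}
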