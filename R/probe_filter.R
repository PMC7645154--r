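#' GC content of a sequence
#'
#' (#G + #C) / length; `N` counts in the denominator only.
#'
#' @param sequence character string over \{A,C,G,T,N\} (case-insensitive).
#' @return proportion in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || nchar(sequence) == 0)
    stop("sequence must be a non-empty string", call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Longest run of characters from an alphabet subset
#'
#' Length of the longest maximal run of consecutive characters that all
#' belong to `alphabet`; a mixed "GCGC" stretch counts as one \{G,C\} run.
#'
#' @param sequence non-empty character string.
#' @param alphabet character vector of single characters.
#' @return integer run length (0 if no character of `alphabet` occurs).
#' @export
max_run <- function(sequence, alphabet) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || nchar(sequence) == 0)
    stop("sequence must be a non-empty string", call. = FALSE)
  if (length(alphabet) == 0)
    stop("alphabet subset must be non-empty", call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1]]
  inset <- chars %in% toupper(alphabet)
  if (!any(inset)) return(0L)
  r <- rle(inset)
  max(r$lengths[r$values])
}

## same-base homopolymer variant: longest run of one repeated base from the
## subset
max_homopolymer_run <- function(sequence, alphabet) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  r <- rle(chars)
  keep <- r$values %in% toupper(alphabet)
  if (!any(keep)) return(0L)
  max(r$lengths[keep])
}

#' Check one SNP's probe context against the flank design rules
#'
#' A site passes iff: GC content of the probe window lies in
#' `[gc_min, gc_max]` (inclusive); no G/C run of length `max_gc_run` or
#' more; no A/T run of length `max_at_run` or more; no other known variant
#' falls inside either flank; and the site is a biallelic SNP. Failures list
#' every violated rule.
#'
#' @param site one-row data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `flank_left`, `flank_right` (and optionally `n_alleles`, `is_snp`).
#' @param neighbors data.frame of known variant positions (`chrom`, `pos`),
#'   normally the pooled candidate set; used for the "only one SNP in the
#'   probe window" rule.
#' @param config a [probe_filter_config()].
#' @return list with `pass` (logical) and `reasons` (character vector among
#'   `gc_content`, `gc_run`, `at_run`, `other_variant`, `not_biallelic`,
#'   `indel`).
#' @export
check_probe <- function(site, neighbors = NULL,
                        config = probe_filter_config()) {
  stopifnot(inherits(config, "probe_filter_config"))
  if (is.na(site$flank_left) || is.na(site$flank_right))
    stop("site flanks are not set; run extract_flanks() first",
         call. = FALSE)
  reasons <- character(0)
  context <- paste0(site$flank_left, site$ref, site$flank_right)
  gc_seq <- if (config$gc_window == "context") context else
    paste0(site$flank_left, site$flank_right)
  gc <- gc_content(gc_seq)
  if (gc < config$gc_min || gc > config$gc_max)
    reasons <- c(reasons, "gc_content")
  runfun <- if (config$combined_run_alphabet) max_run else
    max_homopolymer_run
  if (runfun(context, c("G", "C")) >= config$max_gc_run)
    reasons <- c(reasons, "gc_run")
  if (runfun(context, c("A", "T")) >= config$max_at_run)
    reasons <- c(reasons, "at_run")
  if (config$require_no_other_variant && !is.null(neighbors) &&
      nrow(neighbors) > 0) {
    same <- neighbors$chrom == site$chrom & neighbors$pos != site$pos
    near <- abs(neighbors$pos[same] - site$pos) <= config$flank_length
    if (any(near)) reasons <- c(reasons, "other_variant")
  }
  n_alleles <- if (!is.null(site$n_alleles)) site$n_alleles else 2L
  if (n_alleles != 2L || grepl(",", site$alt, fixed = TRUE))
    reasons <- c(reasons, "not_biallelic")
  if (config$require_no_indel) {
    is_snp <- if (!is.null(site$is_snp)) site$is_snp else
      (nchar(site$ref) == 1L && nchar(gsub(",.*", "", site$alt)) == 1L)
    if (!isTRUE(is_snp)) reasons <- c(reasons, "indel")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Screen all candidate sites for probe compatibility
#'
#' Vectorised [check_probe()] over a candidate table, using the candidate
#' set itself as the neighbouring-variant catalogue. Sites whose state is
#' already `excluded` (e.g. insufficient flank) are passed through
#' unchanged.
#'
#' @param sites candidate data.frame with flanks set (see
#'   [extract_flanks()]).
#' @param config a [probe_filter_config()].
#' @param scores optional externally supplied probe conversion scores: a
#'   data.frame with `chrom`, `pos`, `score`; sites scoring below
#'   `score_min` fail with reason `low_score`. No scorer is implemented
#'   in-package.
#' @param score_min minimum acceptable external score.
#' @return list with `kept` (passing sites, state `candidate`), `rejected`
#'   (failing sites, state `excluded`, with `exclude_reason` listing all
#'   violated rules) and `report` (per-reason counts).
#' @export
filter_probes <- function(sites, config = probe_filter_config(),
                          scores = NULL, score_min = NULL) {
  stopifnot(is.data.frame(sites))
  pre_excluded <- !is.na(sites$state) & sites$state == "excluded"
  reasons <- vector("list", nrow(sites))
  for (i in which(!pre_excluded)) {
    reasons[[i]] <- check_probe(sites[i, , drop = FALSE], sites, config)$reasons
  }
  if (!is.null(scores) && !is.null(score_min)) {
    sc <- scores$score[match(marker_id(sites), marker_id(scores))]
    low <- !is.na(sc) & sc < score_min
    for (i in which(low & !pre_excluded))
      reasons[[i]] <- c(reasons[[i]], "low_score")
  }
  fail <- vapply(reasons, length, integer(1)) > 0 & !pre_excluded
  kept <- sites[!fail & !pre_excluded, , drop = FALSE]
  rejected <- sites[fail | pre_excluded, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$state <- "excluded"
    new_reason <- vapply(reasons[fail | pre_excluded], paste,
                         character(1), collapse = ",")
    old <- rejected$exclude_reason
    rejected$exclude_reason <- ifelse(new_reason == "", old, new_reason)
  }
  all_reasons <- unlist(reasons[fail])
  report <- as.data.frame(table(reason = all_reasons),
                          stringsAsFactors = FALSE)
  names(report) <- c("reason", "n")
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected, report = report)
}
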