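#' Read a CNV segment table
#'
#' Parses a tab-delimited segment table (the shape of SNP-array segmentation
#' output) into a \code{GRanges} with metadata columns \code{sample},
#' \code{markers}, \code{state} and \code{pvalue}. Two coordinate dialects are
#' understood: \code{"tsv"}, the canonical 0-based half-open dialect this
#' package writes, and \code{"partek"}, 1-based fully-closed coordinates as
#' emitted by common segmentation GUIs. Internally coordinates live in the
#' usual Bioconductor 1-based closed convention, so \code{width()} is the
#' fragment size in bp under either dialect.
#'
#' @param path Path to a TSV file with header
#'   \code{sample chrom start end markers state pvalue}.
#' @param dialect \code{"tsv"} (0-based half-open, default) or
#'   \code{"partek"} (1-based inclusive).
#' @return A \code{GRanges}; \code{width(gr)} is the segment size in bp.
#' @details Invalid rows (non-numeric coordinates, \code{end <= start} in the
#'   half-open dialect, bad state or p-value) abort with diagnostics carrying
#'   1-based data row numbers; nothing is silently dropped.
#' @seealso [writeSegments()], [filterSegments()], [buildProfiles()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tchrom\tstart\tend\tmarkers\tstate\tpvalue",
#'              "s1\tchr1\t100\t5100\t25\tloss\t1e-05"), tf)
#' readSegments(tf)
#' @export
readSegments <- function(path, dialect = c("tsv", "partek")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("segment file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "",
                    comment.char = "", check.names = FALSE)
  need <- c("sample", "chrom", "start", "end", "markers", "state", "pvalue")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segment table lacks required column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(tab)
  num <- function(col) suppressWarnings(as.numeric(tab[[col]]))
  start <- num("start"); end <- num("end")
  markers <- num("markers"); pval <- num("pvalue")
  rowErr <- function(bad, what) {
    if (any(bad))
      stop("invalid ", what, " in segment row(s): ",
           paste(which(bad), collapse = ", "))
  }
  rowErr(is.na(start) | is.na(end), "coordinate")
  rowErr(is.na(markers) | markers < 1 | markers != floor(markers),
         "marker count")
  rowErr(is.na(pval) | pval < 0 | pval > 1, "p-value")
  rowErr(!tab$state %in% c("loss", "gain"), "state (must be loss/gain)")
  if (dialect == "tsv") {              # 0-based half-open -> 1-based closed
    rowErr(end <= start, "interval (end <= start)")
    gstart <- start + 1; gend <- end
  } else {                             # 1-based inclusive
    rowErr(end < start, "interval (end < start)")
    gstart <- start; gend <- end
  }
  GRanges(tab$chrom, IRanges(gstart, gend),
          sample = tab$sample,
          markers = as.integer(markers),
          state = factor(tab$state, levels = c("loss", "gain")),
          pvalue = pval)
}

#' Write a CNV segment table in the canonical dialect
#'
#' Emits the package's canonical 0-based half-open TSV; a table written,
#' re-read with [readSegments()] and written again is byte-identical.
#'
#' @param gr Segment \code{GRanges} as returned by [readSegments()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSegments <- function(gr, path) {
  df <- data.frame(
    sample = mcols(gr)$sample,
    chrom = as.character(seqnames(gr)),
    start = format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
    end = format(end(gr), scientific = FALSE, trim = TRUE),
    markers = mcols(gr)$markers,
    state = as.character(mcols(gr)$state),
    pvalue = sprintf("%.6g", mcols(gr)$pvalue),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter CNV segments on size, marker support and call confidence
#'
#' Keeps a segment iff size >= \code{minSize} (inclusive), marker count >=
#' \code{minMarkers} (inclusive) and call p-value < \code{maxP} (strict), the
#' standard reliability filter for SNP-array CNV calls. Order is preserved and
#' the operation is idempotent.
#'
#' @param gr Segment \code{GRanges}.
#' @param minSize Minimum size in bp (default 2000).
#' @param minMarkers Minimum marker count (default 10).
#' @param maxP Strict upper bound on the call p-value (default 0.001).
#' @return The surviving subset of \code{gr}.
#' @export
filterSegments <- function(gr, minSize = 2000, minMarkers = 10,
                           maxP = 0.001) {
  stopifnot(minSize > 0, minMarkers > 0, maxP > 0)
  gr[width(gr) >= minSize &
       mcols(gr)$markers >= minMarkers &
       mcols(gr)$pvalue < maxP]
}

#' Group segments into per-sample size profiles
#'
#' @param gr Filtered segment \code{GRanges}.
#' @return A [CNVProfiles-class] object, one entry per distinct sample, in
#'   order of first appearance.
#' @export
buildProfiles <- function(gr) {
  samp <- mcols(gr)$sample
  ids <- unique(samp)
  sizes <- lapply(ids, function(s) as.numeric(width(gr)[samp == s]))
  names(sizes) <- ids
  new("CNVProfiles", sizes = sizes)
}

#' Read and validate a clinical covariate table
#'
#' Reads the CSV dialect
#' \code{sample,recurrent,followup_months,psadt_months,gleason,nomogram_prob,fusion_count}
#' and validates each record: PSA doubling time (PSADT) may be present only
#' for recurrent patients, Gleason scores must lie in 2..10, the nomogram
#' 7-year progression-free probability in [0, 1], and fusion-transcript counts
#' in 0..8. Non-recurrent patients followed for less than 90 months are kept
#' but flagged ineligible for the non-recurrent comparison arm (column
#' \code{eligible_nonrecurrent}), never silently dropped.
#'
#' @param path CSV path.
#' @return A data.frame, one row per sample, with the typed columns above plus
#'   \code{eligible_nonrecurrent}.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = ",", quote = "",
                    stringsAsFactors = FALSE)
  need <- c("sample", "recurrent", "followup_months", "psadt_months",
            "gleason", "nomogram_prob", "fusion_count")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("clinical table lacks required column(s): ",
         paste(miss, collapse = ", "))
  rec <- tab$recurrent
  if (is.character(rec)) rec <- tolower(rec) %in% c("true", "1", "yes")
  rec <- as.logical(rec)
  psadt <- suppressWarnings(as.numeric(tab$psadt_months))
  fup <- suppressWarnings(as.numeric(tab$followup_months))
  rowErr <- function(bad, what) {
    if (any(bad, na.rm = TRUE))
      stop("invalid ", what, " in clinical row(s): ",
           paste(which(bad), collapse = ", "))
  }
  rowErr(is.na(rec), "recurrence flag")
  rowErr(is.na(fup) | fup < 0, "follow-up")
  rowErr(!rec & !is.na(psadt), "PSADT on a non-recurrent record")
  rowErr(!is.na(psadt) & psadt <= 0, "PSADT (must be positive)")
  gl <- suppressWarnings(as.integer(tab$gleason))
  rowErr(is.na(gl) | gl < 2 | gl > 10, "Gleason score")
  nom <- suppressWarnings(as.numeric(tab$nomogram_prob))
  rowErr(is.na(nom) | nom < 0 | nom > 1, "nomogram probability")
  fus <- suppressWarnings(as.integer(tab$fusion_count))
  rowErr(is.na(fus) | fus < 0 | fus > 8, "fusion count")
  data.frame(sample = as.character(tab$sample), recurrent = rec,
             followup_months = fup, psadt_months = psadt, gleason = gl,
             nomogram_prob = nom, fusion_count = fus,
             eligible_nonrecurrent = !rec & fup >= 90,
             stringsAsFactors = FALSE)
}

#' Write a clinical covariate table
#'
#' Inverse of [readClinical()] (the derived eligibility flag is not written).
#'
#' @param clinical Clinical data.frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  cols <- c("sample", "recurrent", "followup_months", "psadt_months",
            "gleason", "nomogram_prob", "fusion_count")
  df <- clinical[, cols]
  df$recurrent <- ifelse(df$recurrent, "TRUE", "FALSE")
  df$followup_months <- sprintf("%.6g", df$followup_months)
  df$psadt_months <- ifelse(is.na(df$psadt_months), "NA",
                            sprintf("%.6g", df$psadt_months))
  df$nomogram_prob <- sprintf("%.6g", df$nomogram_prob)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' Uses \pkg{rtracklayer} when available, otherwise a minimal reader for the
#' 4-column plain-text BED dialect (chrom, 0-based half-open start/end, name).
#'
#' @param path BED path.
#' @return \code{GRanges} with a \code{name} metadata column.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(mcols(gr)$name))
      mcols(gr)$name <- paste0("region_", seq_along(gr))
    return(gr)
  }
  tab <- read.table(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("BED needs >= 4 columns (chrom, start, end, name)")
  st <- suppressWarnings(as.numeric(tab[[2]]))
  en <- suppressWarnings(as.numeric(tab[[3]]))
  if (any(is.na(st) | is.na(en) | en <= st))
    stop("malformed BED row(s): ",
         paste(which(is.na(st) | is.na(en) | en <= st), collapse = ", "))
  GRanges(tab[[1]], IRanges(st + 1, en), name = as.character(tab[[4]]))
}

#' Read gene sets in GMT format
#'
#' Uses \pkg{fgsea}'s reader when available, else parses the tab-separated
#' GMT dialect directly (set name, description, member genes).
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
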