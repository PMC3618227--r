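#' Interval and scored tracks
#'
#' Tracks (segmental duplications, repeat mask, conservation, known-SNP
#' positions) are carried as `GRanges`. BED and bedGraph files are read and
#' written through rtracklayer, which performs the 0-based half-open to
#' 1-based closed conversion; all in-memory coordinates are 1-based closed.
#'
#' @param path BED (interval track) or bedGraph (scored track) file.
#' @param name track name, attached as metadata.
#' @return a `GRanges`; scored tracks carry a numeric `score` column on the
#'   conventional 0-1000 conservation scale.
#' @export
read_track_bed <- function(path, name = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' @rdname read_track_bed
#' @export
read_track_bedgraph <- function(path, name = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0 | gr$score > 1000)) {
    stop("scored track '", name, "': scores must lie in [0, 1000]")
  }
  if (length(gr) > 1) {
    ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
    if (length(ov)) {
      stop("scored track '", name, "': intervals must not overlap")
    }
  }
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' @param track a `GRanges`.
#' @rdname read_track_bed
#' @export
write_track_bed <- function(track, path) {
  rtracklayer::export(track, path, format = "BED")
  invisible(path)
}

#' @rdname read_track_bed
#' @export
write_track_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

#' Point membership and score lookup in a track
#'
#' `track_membership()` reports, for each 1-based query point, whether it is
#' contained in any interval of the track. `track_score()` additionally
#' returns the score of the covering interval, and 0 for uncovered points
#' (conservation tables omit unaligned bases, which count as unconserved).
#' Queries on chromosomes absent from the track are not members; this is
#' reported once per lookup via a message, not an error.
#'
#' @param track a `GRanges` (scored for `track_score()`).
#' @param chrom,pos parallel vectors of chromosome names and 1-based
#'   positions.
#' @return logical vector (`track_membership`) or numeric vector
#'   (`track_score`).
#' @export
track_membership <- function(track, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  if (any(pos < 1)) stop("positions are 1-based and must be >= 1")
  if (!length(chrom)) return(logical(0))
  known <- as.character(chrom) %in% GenomeInfoDb::seqlevels(track)
  if (any(!known) && length(track)) {
    message(
      "track query on chromosome(s) absent from track: ",
      paste(unique(chrom[!known]), collapse = ", ")
    )
  }
  out <- rep(FALSE, length(chrom))
  if (any(known)) {
    q <- GenomicRanges::GRanges(
      as.character(chrom[known]),
      IRanges::IRanges(start = pos[known], width = 1L)
    )
    out[known] <- GenomicRanges::countOverlaps(q, track) > 0
  }
  out
}

#' @rdname track_membership
#' @export
track_score <- function(track, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  if (any(pos < 1)) stop("positions are 1-based and must be >= 1")
  if (!length(chrom)) return(numeric(0))
  known <- as.character(chrom) %in% GenomeInfoDb::seqlevels(track)
  if (any(!known) && length(track)) {
    message(
      "track query on chromosome(s) absent from track: ",
      paste(unique(chrom[!known]), collapse = ", ")
    )
  }
  out <- rep(0, length(chrom))
  if (any(known)) {
    q <- GenomicRanges::GRanges(
      as.character(chrom[known]),
      IRanges::IRanges(start = pos[known], width = 1L)
    )
    hits <- GenomicRanges::findOverlaps(q, track, select = "first")
    sc <- rep(0, length(q))
    sc[!is.na(hits)] <- track$score[hits[!is.na(hits)]]
    out[known] <- sc
  }
  out
}

#' Build an interval track in memory
#'
#' @param chrom,start,end 1-based closed intervals.
#' @param score optional scores (makes a scored track).
#' @param name track name.
#' @return a `GRanges`.
#' @export
interval_track <- function(chrom, start, end, score = NULL, name = "track") {
  if (any(end < start)) stop("interval track: end < start")
  gr <- GenomicRanges::GRanges(
    as.character(chrom), IRanges::IRanges(start = start, end = end)
  )
  if (!is.null(score)) gr$score <- as.numeric(score)
  S4Vectors::metadata(gr)$name <- name
  gr
}
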