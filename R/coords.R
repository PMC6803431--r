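#' Signed cDNA coordinates
#'
#' Positions along the cDNA are expressed in a signed, 1-based convention
#' anchored at the translation start: position 1 is the first base of the
#' coding sequence, position -1 the base immediately 5' of it, and position 0
#' does not exist.  Spans are inclusive at both ends.  This convention lets a
#' single integer place a primer either in the 5' leader (negative values) or
#' in the coding region (positive values) and makes amplicon sizes computable
#' directly from printed primer spans.
#'
#' @name signed-coords
NULL

assert_signed_coord <- function(x, arg = deparse(substitute(x))) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x)) {
    stop(sprintf("`%s` must be a single integer coordinate", arg),
         call. = FALSE)
  }
  if (x == 0) {
    stop(sprintf("`%s` is 0: position 0 does not exist in signed cDNA coordinates",
                 arg), call. = FALSE)
  }
  as.integer(x)
}

#' Length of an inclusive signed-coordinate span
#'
#' Computes the number of bases covered by the inclusive span
#' `[start, end]` under the signed convention (see [signed-coords]).  When
#' the span crosses the translation start (`start < 0 < end`) the nonexistent
#' position 0 is skipped, so the length is `end - start`; otherwise it is
#' `end - start + 1`.
#'
#' @param start,end Signed coordinates with `start <= end`; neither may be 0.
#' @return Integer span length in bases.
#' @examples
#' signed_span_length(409, 558)  # 150
#' signed_span_length(-26, 751)  # 777 (position 0 skipped)
#' signed_span_length(-3, 3)     # 6
#' @export
signed_span_length <- function(start, end) {
  start <- assert_signed_coord(start)
  end <- assert_signed_coord(end)
  if (start > end) {
    stop("span start must not follow span end in signed order", call. = FALSE)
  }
  if (start < 0 && end > 0) end - start else end - start + 1L
}

# Map a signed coordinate to a 1-based index into a sequence string that
# carries `utr5_len` leader bases before the coding sequence.
signed_to_index <- function(pos, utr5_len) {
  pos <- assert_signed_coord(pos)
  idx <- if (pos > 0) utr5_len + pos else utr5_len + pos + 1L
  if (idx < 1L) {
    stop(sprintf("coordinate %d lies 5' of the available sequence (leader length %d)",
                 pos, utr5_len), call. = FALSE)
  }
  as.integer(idx)
}

# Inverse of signed_to_index for a raw 1-based string position.
index_to_signed <- function(idx, utr5_len) {
  ifelse(idx > utr5_len, idx - utr5_len, idx - utr5_len - 1L)
}
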