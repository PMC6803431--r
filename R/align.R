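#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment of two nucleotide sequences under a simple
#' match/mismatch/linear-gap scoring scheme.  Ties during traceback are
#' broken deterministically in the order diagonal > up (gap in `seq_b`) >
#' left (gap in `seq_a`), so identical inputs always yield the identical
#' alignment.
#'
#' The two parental cDNAs this package compares are equal-length
#' substitution-only variants of one another, for which any sensible scheme
#' returns the ungapped alignment; the defaults (match 1, mismatch -1,
#' gap -2) are standard for such closely related sequences.
#'
#' @param seq_a,seq_b Nonempty ACGT/N strings.
#' @param match,mismatch,gap Scoring parameters (linear gap penalty).
#' @return An object of class `pairwise_alignment`: a list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length) and `score`.
#' @examples
#' align_pair("ACGT", "AGGT")$score  # 2
#' @export
align_pair <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  for (s in c(seq_a, seq_b)) {
    if (!is.character(s) || length(s) != 1L || !grepl("^[ACGTNacgtn]+$", s)) {
      stop("sequences must be nonempty ACGT/N strings", call. = FALSE)
    }
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  n <- length(a)
  m <- length(b)

  S <- matrix(0, n + 1L, m + 1L)
  # pointer codes: 1 diagonal, 2 up (consume a, gap in b), 3 left (gap in a)
  P <- matrix(0L, n + 1L, m + 1L)
  S[1L, ] <- gap * (0:m)
  S[, 1L] <- gap * (0:n)
  P[1L, -1L] <- 3L
  P[-1L, 1L] <- 2L
  for (i in seq_len(n)) {
    sub <- ifelse(b == a[i], match, mismatch)
    for (j in seq_len(m)) {
      d <- S[i, j] + sub[j]
      u <- S[i, j + 1L] + gap
      l <- S[i + 1L, j] + gap
      if (d >= u && d >= l) {
        S[i + 1L, j + 1L] <- d
        P[i + 1L, j + 1L] <- 1L
      } else if (u >= l) {
        S[i + 1L, j + 1L] <- u
        P[i + 1L, j + 1L] <- 2L
      } else {
        S[i + 1L, j + 1L] <- l
        P[i + 1L, j + 1L] <- 3L
      }
    }
  }

  # traceback
  i <- n + 1L
  j <- m + 1L
  ra <- character(0)
  rb <- character(0)
  while (i > 1L || j > 1L) {
    move <- P[i, j]
    if (move == 1L) {
      ra <- c(a[i - 1L], ra)
      rb <- c(b[j - 1L], rb)
      i <- i - 1L
      j <- j - 1L
    } else if (move == 2L) {
      ra <- c(a[i - 1L], ra)
      rb <- c("-", rb)
      i <- i - 1L
    } else {
      ra <- c("-", ra)
      rb <- c(b[j - 1L], rb)
      j <- j - 1L
    }
  }

  structure(
    list(aligned_a = paste(ra, collapse = ""),
         aligned_b = paste(rb, collapse = ""),
         score = S[n + 1L, m + 1L],
         match = match, mismatch = mismatch, gap = gap),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %g\n", x$score))
  cat("  A: ", x$aligned_a, "\n  B: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Call fixed differences from a pairwise alignment
#'
#' Scans an alignment of the maternal-line (A) versus paternal-line (B)
#' cDNA and reports every column where both sequences carry a base and the
#' bases differ, as [snp_site()]-style records.  Positions are reported in
#' the signed coordinates of sequence A (see [signed-coords]); columns with
#' a gap in either sequence are collected separately as indels and are never
#' reported as SNPs.  For a column with a gap in A, the reported position is
#' that of the last preceding A base.
#'
#' @param alignment A [align_pair()] result.
#' @param utr5_len Number of leader bases in sequence A preceding coding
#'   position 1 (default 0, i.e. the sequence starts at the coding start).
#' @return An object of class `fixed_differences`: a list with `snps`
#'   (data frame: `position`, `nile_allele`, `blue_allele`) and `indels`
#'   (data frame: `position`, `nile_base`, `blue_base`).
#' @export
call_fixed_differences <- function(alignment, utr5_len = 0L) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  apos <- cumsum(ca != "-")
  signed <- index_to_signed(pmax(apos, 1L), utr5_len)
  is_indel <- ca == "-" | cb == "-"
  is_snp <- !is_indel & ca != cb
  structure(
    list(
      snps = data.frame(position = as.integer(signed[is_snp]),
                        nile_allele = ca[is_snp],
                        blue_allele = cb[is_snp],
                        stringsAsFactors = FALSE),
      indels = data.frame(position = as.integer(signed[is_indel]),
                          nile_base = ca[is_indel],
                          blue_base = cb[is_indel],
                          stringsAsFactors = FALSE)
    ),
    class = "fixed_differences"
  )
}

#' @export
print.fixed_differences <- function(x, ...) {
  cat(sprintf("<fixed_differences> %d SNP(s), %d indel column(s)\n",
              nrow(x$snps), nrow(x$indels)))
  if (nrow(x$snps)) print(x$snps, row.names = FALSE)
  invisible(x)
}

# Normalize an observed Sanger base call to a set of bases: either a vector
# of A/C/G/T characters or a single IUPAC ambiguity letter ("S" -> C,G).
normalize_base_set <- function(observed) {
  observed <- toupper(observed)
  if (length(observed) == 1L && !observed %in% c("A", "C", "G", "T")) {
    code <- Biostrings::IUPAC_CODE_MAP[observed]
    if (is.na(code)) {
      stop(sprintf("unknown base or ambiguity code '%s'", observed),
           call. = FALSE)
    }
    observed <- strsplit(code, "", fixed = TRUE)[[1]]
  }
  bases <- sort(unique(observed))
  if (!all(bases %in% c("A", "C", "G", "T")) ||
      length(bases) < 1L || length(bases) > 2L) {
    stop("observed bases must be 1-2 distinct A/C/G/T bases", call. = FALSE)
  }
  bases
}

#' Genotype an individual at a diagnostic SNP site
#'
#' Interprets a Sanger trace observation at a fixed-difference site.  The
#' observation may be a single base, an unordered pair of bases, or one
#' IUPAC ambiguity letter (e.g. `"S"` for C/G).  A single maternal-line
#' allele is a homozygous maternal-type call, a single paternal-line allele
#' homozygous paternal-type, and both alleles together a heterozygous call
#' (the expected F1 hybrid genotype).  Any base not among the site's two
#' alleles is an error.
#'
#' @param observed Character vector of observed bases, or one IUPAC letter.
#' @param site A [snp_site()].
#' @param individual Optional individual identifier carried into the call.
#' @return An object of class `genotype_call`: list with `individual`,
#'   `position`, `observed`, `zygosity` ("homozygous"/"heterozygous") and
#'   `origin` ("maternal", "paternal" or "both").
#' @export
genotype_at_site <- function(observed, site, individual = NA_character_) {
  stopifnot(inherits(site, "snp_site"))
  bases <- normalize_base_set(observed)
  alleles <- c(site$nile_allele, site$blue_allele)
  if (!all(bases %in% alleles)) {
    stop(sprintf("observed base(s) %s incompatible with a %s/%s site",
                 paste(bases, collapse = "/"), alleles[1], alleles[2]),
         call. = FALSE)
  }
  zygosity <- if (length(bases) == 2L) "heterozygous" else "homozygous"
  origin <- if (length(bases) == 2L) {
    "both"
  } else if (bases == site$nile_allele) {
    "maternal"
  } else {
    "paternal"
  }
  structure(
    list(individual = individual, position = site$position,
         observed = bases, zygosity = zygosity, origin = origin),
    class = "genotype_call"
  )
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> position %d: %s (%s, %s)\n",
              x$position, paste(x$observed, collapse = "/"),
              x$zygosity, x$origin))
  invisible(x)
}
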