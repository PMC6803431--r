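#' Construct a primer pair
#'
#' Bundles a forward/reverse primer pair with its signed template spans
#' (see [signed-coords]).  Each primer sequence must have exactly the length
#' of its span; the forward span must lie entirely 5' of the reverse span.
#' The annealing temperature is carried as pass-through metadata.
#'
#' @param name Primer pair name.
#' @param forward_seq,reverse_seq Primer sequences (5' to 3', ACGT/N).  The
#'   reverse primer is given as its own sequence, i.e. the reverse complement
#'   of the template span it covers.
#' @param forward_span,reverse_span Length-2 integer vectors of signed
#'   coordinates `c(start, end)`.
#' @param tm_c Annealing temperature in degrees Celsius (optional metadata).
#' @return An object of class `primer_pair`.
#' @examples
#' rt_gh <- primer_pair("rt-GH",
#'   forward_seq = "ATCAGGGCCAATCAGGATGA", forward_span = c(409, 428),
#'   reverse_seq = "GTGCATGTCCTTCTTGAAGCAA", reverse_span = c(537, 558))
#' amplicon_size(rt_gh)  # 150
#' @export
primer_pair <- function(name, forward_seq, forward_span,
                        reverse_seq, reverse_span, tm_c = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  forward_seq <- toupper(forward_seq)
  reverse_seq <- toupper(reverse_seq)
  for (s in c(forward_seq, reverse_seq)) {
    if (!grepl("^[ACGTN]+$", s)) {
      stop("primer sequences must be nonempty ACGT/N strings", call. = FALSE)
    }
  }
  check_span <- function(span, seq, what) {
    if (length(span) != 2L) {
      stop(sprintf("%s span must be c(start, end)", what), call. = FALSE)
    }
    len <- signed_span_length(span[1], span[2])
    if (len != nchar(seq)) {
      stop(sprintf("%s primer length (%d) does not match its span length (%d)",
                   what, nchar(seq), len), call. = FALSE)
    }
    as.integer(span)
  }
  forward_span <- check_span(forward_span, forward_seq, "forward")
  reverse_span <- check_span(reverse_span, reverse_seq, "reverse")
  if (forward_span[2] >= reverse_span[1]) {
    stop("forward span must lie entirely 5' of the reverse span", call. = FALSE)
  }
  structure(
    list(name = name,
         forward_seq = forward_seq, forward_span = forward_span,
         reverse_seq = reverse_seq, reverse_span = reverse_span,
         tm_c = tm_c),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n", x$name))
  cat(sprintf("  forward %s (%d..%d)\n", x$forward_seq,
              x$forward_span[1], x$forward_span[2]))
  cat(sprintf("  reverse %s (%d..%d)\n", x$reverse_seq,
              x$reverse_span[1], x$reverse_span[2]))
  cat(sprintf("  amplicon %d bp\n", amplicon_size(x)))
  invisible(x)
}

#' Amplicon size of a primer pair
#'
#' The amplicon runs from the first base of the forward primer to the last
#' base of the template span covered by the reverse primer, inclusive, under
#' the signed zero-skipping convention.
#'
#' @param pair A [primer_pair()].
#' @return Integer amplicon length in bp.
#' @export
amplicon_size <- function(pair) {
  stopifnot(inherits(pair, "primer_pair"))
  signed_span_length(pair$forward_span[1], pair$reverse_span[2])
}

#' Locate a SNP site within an amplicon
#'
#' Reports the 1-based offset of a SNP site from the first base of the
#' amplicon (the forward primer's first base counts as offset 1), or flags
#' the site as outside the amplicon.  Used to confirm that an
#' allele-quantification assay actually covers its target site.
#'
#' @param site A [snp_site()] or a single signed coordinate.
#' @param pair A [primer_pair()].
#' @return A list with elements `inside` (logical) and `offset` (integer or
#'   `NA` when outside).
#' @export
site_in_amplicon <- function(site, pair) {
  stopifnot(inherits(pair, "primer_pair"))
  pos <- if (inherits(site, "snp_site")) site$position else site
  pos <- assert_signed_coord(pos)
  lo <- pair$forward_span[1]
  hi <- pair$reverse_span[2]
  if (pos < lo || pos > hi) {
    return(list(inside = FALSE, offset = NA_integer_))
  }
  list(inside = TRUE, offset = signed_span_length(lo, pos))
}

#' Construct a SNP site
#'
#' One fixed difference between the two parental lines: a signed cDNA
#' position plus the allele carried by each line.  Line "N" is the maternal
#' (Nile tilapia) line and "B" the paternal (blue tilapia) line throughout.
#'
#' @param position Signed cDNA coordinate (never 0).
#' @param nile_allele,blue_allele Single bases; must differ.
#' @return An object of class `snp_site`.
#' @export
snp_site <- function(position, nile_allele, blue_allele) {
  position <- assert_signed_coord(position)
  nile_allele <- toupper(nile_allele)
  blue_allele <- toupper(blue_allele)
  for (a in c(nile_allele, blue_allele)) {
    if (!a %in% c("A", "C", "G", "T")) {
      stop("alleles must be single A/C/G/T bases", call. = FALSE)
    }
  }
  if (nile_allele == blue_allele) {
    stop("the two parental alleles must differ at a SNP site", call. = FALSE)
  }
  structure(list(position = position, nile_allele = nile_allele,
                 blue_allele = blue_allele),
            class = "snp_site")
}

#' Read a primer table
#'
#' Reads a TSV with columns `pair`, `role` (forward/reverse/sequencing),
#' `name`, `seq`, `start`, `end`, and optionally `tm_c` and `usage`, and
#' assembles [primer_pair()] objects from rows sharing a `pair` value with
#' forward and reverse roles.  Rows with role `sequencing` (single internal
#' sequencing primers) are returned separately.
#'
#' @param path Path to the TSV file.
#' @return A list with `pairs` (named list of `primer_pair`) and
#'   `sequencing` (data frame of single primers).
#' @export
read_primer_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("pair", "role", "name", "seq", "start", "end")
  if (!all(needed %in% names(tab))) {
    stop("primer table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  seq_rows <- tab[tab$role == "sequencing", , drop = FALSE]
  tab <- tab[tab$role %in% c("forward", "reverse"), , drop = FALSE]
  pairs <- list()
  for (pn in unique(tab$pair)) {
    fw <- tab[tab$pair == pn & tab$role == "forward", ]
    rv <- tab[tab$pair == pn & tab$role == "reverse", ]
    if (nrow(fw) != 1L || nrow(rv) != 1L) {
      stop(sprintf("primer pair '%s' must have exactly one forward and one reverse row", pn),
           call. = FALSE)
    }
    tm <- if ("tm_c" %in% names(fw)) as.numeric(fw$tm_c) else NA_real_
    pairs[[pn]] <- primer_pair(pn,
                               forward_seq = fw$seq,
                               forward_span = c(fw$start, fw$end),
                               reverse_seq = rv$seq,
                               reverse_span = c(rv$start, rv$end),
                               tm_c = tm)
  }
  list(pairs = pairs, sequencing = seq_rows)
}

#' The packaged growth-hormone assay primer set
#'
#' The primer pairs used throughout the worked examples: a cloning pair whose
#' forward primer sits in the 5' leader (span -26..-8), a qPCR pair for the
#' GH target, a qPCR pair for the beta-actin reference gene, and the
#' pyrosequencing PCR pair that brackets the diagnostic C/G site at
#' position 501.
#'
#' @return A named list of [primer_pair()] objects
#'   (`GH`, `rt-GH`, `rt-actin`, `pyr-GH`).
#' @export
gh_primer_set <- function() {
  path <- system.file("extdata", "gh_primers.tsv", package = "hybridase",
                      mustWork = TRUE)
  read_primer_table(path)$pairs
}
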