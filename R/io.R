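#' Genomic interval
#'
#' 0-based half-open interval on a named chromosome, the coordinate
#' convention used throughout (BED convention).
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds in bp, `0 <= start < end`.
#' @return A `ccm_interval` list.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1, start >= 0, start < end)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end)), class = "ccm_interval")
}

#' Read a ChromHMM segmentation into a per-bead annotation
#'
#' Bins the region into `bead_bp`-sized beads (bead k covers
#' `[start + k*bead_bp, start + (k+1)*bead_bp)`), assigns each bead the
#' ChromHMM state with the largest overlap (ties broken toward the
#' lower-numbered state), then collapses states 1-11 to the active label A
#' and states 12-15 to the repressive label B. Strand is ignored. The bead
#' count is `floor(region length / bead_bp)`.
#'
#' The BED name field must contain the state number, either bare ("5") or in
#' the common "5_TxnElongation" / "E5" forms.
#'
#' @param path BED file path.
#' @param region a [genomic_interval()] to model.
#' @param params a [ccm_parameters()] providing `bead_bp`.
#' @param uncovered policy for beads with no overlapping record: "error"
#'   (default) or a state number (1-15) used as fill.
#' @return A [epigenome_annotation()].
#' @export
read_chromhmm_bed <- function(path, region, params, uncovered = "error") {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 4) stop("malformed BED: need chrom, start, end, state")
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  if (!is.numeric(bed$start) || !is.numeric(bed$end) ||
      any(bed$start >= bed$end))
    stop("malformed BED line: invalid coordinates")
  state <- parse_state(bed$name)
  bed <- bed[bed$chrom == region$chrom, ]
  state <- state[seq_len(nrow(bed))]
  bead_bp <- params$bead_bp
  nb <- floor((region$end - region$start) / bead_bp)
  if (nb < 1) stop("region shorter than one bead")
  states_out <- integer(nb)
  for (k in seq_len(nb)) {
    lo <- region$start + (k - 1) * bead_bp
    hi <- lo + bead_bp
    ov <- pmin(bed$end, hi) - pmax(bed$start, lo)
    sel <- ov > 0
    if (!any(sel)) {
      if (identical(uncovered, "error"))
        stop(sprintf("bead %d (bp %g-%g) not covered by any BED record",
                     k, lo, hi))
      states_out[k] <- as.integer(uncovered)
      next
    }
    per_state <- tapply(ov[sel], state[sel], sum)
    best <- max(per_state)
    # tie-break toward the lower-numbered state
    states_out[k] <- min(as.integer(names(per_state)[per_state == best]))
  }
  labels <- ifelse(states_out <= 11, "A", "B")
  epigenome_annotation(labels, states = states_out, chrom = region$chrom,
                       start = region$start, bead_bp = bead_bp)
}

parse_state <- function(name) {
  s <- sub("^E", "", as.character(name))
  s <- sub("_.*$", "", s)
  st <- suppressWarnings(as.integer(s))
  if (any(is.na(st)) || any(st < 1 | st > 15))
    stop("malformed BED: cannot parse a ChromHMM state (1-15) from the name field")
  st
}

#' Read loop-anchor pairs from a BEDPE file
#'
#' Each record's two anchor intervals are mapped to the beads containing
#' their midpoints. Records with either anchor outside the region are
#' dropped; pairs mapping to the same bead or to adjacent beads are dropped
#' with a warning; duplicates are collapsed.
#'
#' @param path BEDPE file path (chrom1 start1 end1 chrom2 start2 end2 ...).
#' @param region a [genomic_interval()].
#' @param params a [ccm_parameters()] providing `bead_bp`.
#' @return A [loop_set()] on `floor(region length / bead_bp)` beads.
#' @export
read_loops_bedpe <- function(path, region, params) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6) stop("malformed BEDPE: need 6 coordinate columns")
  names(df)[1:6] <- c("c1", "s1", "e1", "c2", "s2", "e2")
  if (any(df$s1 >= df$e1) || any(df$s2 >= df$e2))
    stop("malformed BEDPE record: invalid anchor coordinates")
  bead_bp <- params$bead_bp
  nb <- floor((region$end - region$start) / bead_bp)
  mid1 <- (df$s1 + df$e1) / 2
  mid2 <- (df$s2 + df$e2) / 2
  b1 <- floor((mid1 - region$start) / bead_bp) + 1
  b2 <- floor((mid2 - region$start) / bead_bp) + 1
  keep <- df$c1 == region$chrom & df$c2 == region$chrom &
    b1 >= 1 & b1 <= nb & b2 >= 1 & b2 <= nb
  b1 <- b1[keep]; b2 <- b2[keep]
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  close_pairs <- hi - lo < 2
  if (any(close_pairs))
    warning(sprintf("%d loop record(s) map to the same or adjacent beads; dropped",
                    sum(close_pairs)))
  lo <- lo[!close_pairs]; hi <- hi[!close_pairs]
  loop_set(cbind(lo, hi), nb)
}

#' Contact matrix container
#'
#' Square symmetric non-negative matrix of contact counts or probabilities
#' with its genomic metadata.
#'
#' @param mat square numeric matrix.
#' @param bin_bp bin size in bp.
#' @param kind "counts" or "probability" (probability entries must lie in
#'   `[0, 1]`).
#' @param chrom,start genomic origin of bin 1.
#' @return A `ccm_contact_matrix`.
#' @export
contact_matrix <- function(mat, bin_bp = 1200, kind = c("counts", "probability"),
                           chrom = NA_character_, start = 0) {
  kind <- match.arg(kind)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix must be square")
  if (any(mat < 0)) stop("contact matrix must be non-negative")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat))))
    stop("contact matrix must be symmetric")
  if (kind == "probability" && any(mat > 1))
    stop("probability contact matrix has entries > 1")
  structure(list(mat = mat, bin_bp = bin_bp, kind = kind, chrom = chrom,
                 start = start), class = "ccm_contact_matrix")
}

#' Read / write a contact matrix as dense TSV
#'
#' The TSV carries a `# bin_bp=... kind=...` header comment followed by the
#' dense matrix. Round-tripping a matrix through `write_contact_matrix()`
#' and `read_contact_matrix()` is bit-exact.
#'
#' @param path file path.
#' @param format only "tsv" is supported (dense text matrix).
#' @return `read_contact_matrix` returns a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = "tsv") {
  if (!identical(format, "tsv"))
    stop("only the dense TSV format is supported")
  first <- readLines(path, n = 1)
  bin_bp <- 1200; kind <- "counts"; skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1]]
    for (f in kv) {
      p <- strsplit(f, "=")[[1]]
      if (p[1] == "bin_bp") bin_bp <- as.numeric(p[2])
      if (p[1] == "kind") kind <- p[2]
    }
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   skip = skip))
  dimnames(m) <- NULL
  contact_matrix(m, bin_bp = bin_bp, kind = kind)
}

#' @rdname read_contact_matrix
#' @param x a [contact_matrix()].
#' @export
write_contact_matrix <- function(x, path, format = "tsv") {
  if (!identical(format, "tsv"))
    stop("only the dense TSV format is supported")
  stopifnot(inherits(x, "ccm_contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_bp=%.10g kind=%s", x$bin_bp, x$kind), con)
  utils::write.table(format(x$mat, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
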