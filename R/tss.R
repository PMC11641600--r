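#' Read TSS coordinates from a BED6 file
#'
#' Each record anchors one gene's transcription start site; the strand
#' column is required.  When a record is wider than one base, the TSS is
#' taken as its 5' end in transcript orientation (leftmost base on `+`,
#' rightmost on `-`).
#'
#' @param path BED file with name and strand columns.
#' @return A `GRanges` of the TSS records.
#' @export
read_tss_bed <- function(path) {
  if (!file.exists(path)) validation_error("TSS BED not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (any(as.character(BiocGenerics::strand(gr)) == "*"))
    validation_error("%s: every TSS record needs a strand (+/-)", path)
  if (is.null(gr$name) || anyNA(gr$name))
    validation_error("%s: every TSS record needs a name", path)
  gr
}

#' Read aligned fragments from a BED file
#'
#' Three or more columns; only chromosome, start and end are used.
#'
#' @param path BED file of aligned fragments.
#' @return A `GRanges` of the fragments.
#' @export
read_fragments_bed <- function(path) {
  if (!file.exists(path)) validation_error("fragment BED not found: %s", path)
  rtracklayer::import(path, format = "BED")
}

#' Bin layout around transcription start sites
#'
#' Tiles the window `[TSS - flank, TSS + flank)` of every gene with
#' `n_bins` contiguous half-open bins of equal length `2 * flank / n_bins`
#' (0-based genomic coordinates).  Bins are ordered 5' to 3' in transcript
#' orientation: for a minus-strand gene, bin 1 covers the genomically
#' rightmost interval, so "upstream" always means upstream of
#' transcription.  Windows running past the chromosome start are kept but
#' flagged: the number of (partly) out-of-range bins is recorded per gene
#' and their counts are necessarily zero.
#'
#' Common layouts: `flank = 5000, n_bins = 100` (100-bp bins over +-5 kb)
#' and `flank = 3000, n_bins = 60` (100-bp bins over +-3 kb).
#'
#' @param tss a `GRanges` from [read_tss_bed()], or a data.frame with
#'   columns `name`, `chrom`, `pos` (0-based TSS coordinate) and `strand`.
#' @param flank bases on each side of the TSS.
#' @param n_bins even positive bin count; `2 * flank` must be divisible by
#'   `n_bins`.
#' @return A `bin_layout`: per-gene table (`name`, `chrom`, `tss0`,
#'   `strand`, `n_clipped_bins`), `flank`, `n_bins`, `bin_len`.
#' @export
make_bin_layout <- function(tss, flank = 5000L, n_bins = 100L) {
  if (n_bins <= 0L || n_bins %% 2L != 0L)
    validation_error("n_bins must be a positive even integer")
  if ((2L * flank) %% n_bins != 0L)
    validation_error("2 * flank (%d) must be divisible by n_bins (%d)",
                     2L * flank, n_bins)
  if (is(tss, "GRanges")) {
    strand <- as.character(BiocGenerics::strand(tss))
    start0 <- BiocGenerics::start(tss) - 1L
    end0 <- BiocGenerics::end(tss)
    genes <- data.frame(
      name = as.character(tss$name),
      chrom = as.character(GenomicRanges::seqnames(tss)),
      tss0 = ifelse(strand == "+", start0, end0 - 1L),
      strand = strand,
      stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(name = as.character(tss$name),
                        chrom = as.character(tss$chrom),
                        tss0 = as.integer(tss$pos),
                        strand = as.character(tss$strand),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$name))
    validation_error("duplicated gene names in TSS input")
  bin_len <- 2L * flank / n_bins
  under <- pmax(0L, flank - genes$tss0)
  genes$n_clipped_bins <- as.integer(ceiling(under / bin_len))
  structure(list(genes = genes, flank = as.integer(flank),
                 n_bins = as.integer(n_bins), bin_len = bin_len),
            class = "bin_layout")
}

#' Genomic bin boundaries of one gene in a layout
#'
#' Returns the `n_bins + 1` half-open 0-based boundaries in genomic order
#' (increasing coordinate); for minus-strand genes the transcript-oriented
#' bin `j` maps to genomic bin `n_bins + 1 - j`.
#'
#' @param layout a `bin_layout`.
#' @param gene gene name.
#' @return Integer vector of boundaries.
#' @export
bin_boundaries <- function(layout, gene) {
  stopifnot(inherits(layout, "bin_layout"))
  g <- layout$genes[layout$genes$name == gene, ]
  if (!nrow(g)) validation_error("gene '%s' not in layout", gene)
  (g$tss0 - layout$flank) + layout$bin_len * (0:layout$n_bins)
}

#' Count fragment midpoints per TSS bin
#'
#' Each fragment is assigned to the single bin containing its midpoint
#' (0-based `floor((start + end) / 2)`), so every fragment counts at most
#' once per gene window; a midpoint sitting exactly on a boundary belongs
#' to the bin to its right (half-open convention).
#'
#' @param fragments a `GRanges` from [read_fragments_bed()] (or any
#'   `GRanges`).
#' @param layout a `bin_layout`.
#' @return Integer matrix, genes x bins, rows named by gene, bins in
#'   transcript orientation.
#' @export
count_fragments <- function(fragments, layout) {
  stopifnot(is(fragments, "GRanges"), inherits(layout, "bin_layout"))
  frag_chr <- as.character(GenomicRanges::seqnames(fragments))
  if (length(fragments) &&
      !any(unique(layout$genes$chrom) %in% unique(frag_chr)))
    validation_error(
      "no chromosome shared between fragments (%s) and TSS layout (%s)",
      paste(unique(frag_chr), collapse = ","),
      paste(unique(layout$genes$chrom), collapse = ","))
  ## 0-based fragment midpoints per chromosome, sorted
  mid0 <- floor((BiocGenerics::start(fragments) - 1L +
                 BiocGenerics::end(fragments)) / 2)
  mids <- split(mid0, frag_chr)
  mids <- lapply(mids, sort)
  nb <- layout$n_bins
  counts <- matrix(0L, nrow(layout$genes), nb,
                   dimnames = list(layout$genes$name, NULL))
  for (i in seq_len(nrow(layout$genes))) {
    g <- layout$genes[i, ]
    mv <- mids[[g$chrom]]
    if (is.null(mv) || !length(mv)) next
    breaks <- (g$tss0 - layout$flank) + layout$bin_len * (0:nb)
    ## below(t) = number of midpoints < t; integer coords allow t - 0.5
    below <- findInterval(breaks - 0.5, mv)
    cnt <- diff(below)
    if (g$strand == "-") cnt <- rev(cnt)
    counts[i, ] <- cnt
  }
  counts
}

#' Depth- and length-normalized binned signal
#'
#' Normalizes raw bin counts to
#' \eqn{H_{ijl} = h_{ijl} \times 10^9 / (h_l \times L_j)} where \eqn{h_l}
#' is the sample's sequencing depth (total fragments) and \eqn{L_j} the bin
#' length, then averages across samples:
#' \eqn{H_{ij} = \frac{1}{m}\sum_l H_{ijl}}.  The \eqn{10^9} keeps the
#' values on a TPM-like magnitude.  Scaling a sample's counts and depth by
#' the same factor leaves \eqn{H} unchanged.
#'
#' @param counts genes x bins count matrix, or a list of such matrices
#'   (one per replicate sample).
#' @param depth sequencing depth per sample (positive; recycled rules not
#'   applied -- length must match).
#' @param layout the `bin_layout` the counts were made with.
#' @return A `binned_signal`: `per_sample` list of normalized matrices,
#'   their average `mean`, `depth`, and the `layout`.
#' @export
normalize_signal <- function(counts, depth, layout) {
  stopifnot(inherits(layout, "bin_layout"))
  if (is.matrix(counts)) counts <- list(counts)
  if (length(depth) != length(counts))
    validation_error("need one depth per count matrix (%d vs %d)",
                     length(depth), length(counts))
  if (any(depth <= 0)) validation_error("sequencing depth must be positive")
  H <- mapply(function(h, hl) h * 1e9 / (hl * layout$bin_len),
              counts, depth, SIMPLIFY = FALSE)
  structure(list(per_sample = H,
                 mean = Reduce(`+`, H) / length(H),
                 depth = depth, layout = layout),
            class = "binned_signal")
}

#' TSS metagene profile from fragment BED files
#'
#' Convenience wrapper: reads each sample's fragments, counts midpoints in
#' the layout bins, uses the total fragment count of each file as its
#' sequencing depth, and normalizes.  One call per histone mark.
#'
#' @param fragment_paths named character vector of fragment BED paths
#'   (names become sample ids).
#' @param tss TSS input accepted by [make_bin_layout()].
#' @param flank,n_bins layout parameters.
#' @return A `binned_signal` (see [normalize_signal()]); per-sample
#'   matrices are named by sample.
#' @export
tss_profile <- function(fragment_paths, tss, flank = 5000L, n_bins = 100L) {
  layout <- make_bin_layout(tss, flank = flank, n_bins = n_bins)
  frags <- lapply(fragment_paths, read_fragments_bed)
  counts <- lapply(frags, count_fragments, layout = layout)
  depth <- vapply(frags, length, integer(1))
  sig <- normalize_signal(counts, depth, layout)
  names(sig$per_sample) <- names(fragment_paths)
  sig
}

#' Write a binned signal matrix
#'
#' Writes the cross-sample average (and optionally each sample's matrix)
#' as gene x bin TSVs.
#'
#' @param signal a `binned_signal`.
#' @param path output TSV for the averaged matrix.
#' @param per_sample_dir optional directory for per-sample matrices.
#' @export
write_binned_signal <- function(signal, path, per_sample_dir = NULL) {
  stopifnot(inherits(signal, "binned_signal"))
  emit <- function(mat, p) {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    colnames(df) <- c("gene", paste0("bin", seq_len(ncol(mat))))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  emit(signal$mean, path)
  if (!is.null(per_sample_dir)) {
    dir.create(per_sample_dir, showWarnings = FALSE, recursive = TRUE)
    nm <- names(signal$per_sample)
    if (is.null(nm)) nm <- paste0("sample", seq_along(signal$per_sample))
    for (i in seq_along(signal$per_sample))
      emit(signal$per_sample[[i]], file.path(per_sample_dir, paste0(nm[i], ".tsv")))
  }
  invisible(path)
}
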