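#' Count qualifying variants per fixed genomic bin
#'
#' Bins are fixed-width windows anchored at coordinate 1 (bin index
#' `floor((pos - 1) / bin_size)`), so position 1,000,000 falls in bin 0 and
#' 1,000,001 in bin 1 at the default 1 Mbp width. Every chromosome in
#' `genome` is emitted in full, zero bins included, so tracks from
#' different pools line up.
#'
#' @param vs A `variant_set` with zygosity computed.
#' @param genome A data frame with columns `chrom` and `length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp (default 1e6).
#' @param predicate Which variants qualify: `"homozygous"` (all homozygous
#'   variant positions) or `"homozygous_ems"` (additionally canonical EMS
#'   SNVs only).
#' @return A tibble of class `bin_track` with columns `chrom`,
#'   `bin_index` (0-based), `bin_start`, `bin_end` (1-based inclusive) and
#'   `count`; attribute `bin_size`.
#' @export
bin_variants <- function(vs, genome, bin_size = 1e6,
                         predicate = c("homozygous", "homozygous_ems")) {
  predicate <- match.arg(predicate)
  if (is.numeric(genome))
    genome <- tibble::tibble(chrom = names(genome), length = unname(genome))
  stopifnot(all(c("chrom", "length") %in% names(genome)))

  qual <- vs$zygosity == "homozygous"
  if (predicate == "homozygous_ems")
    qual <- qual & !vs$is_indel & is_canonical_ems(vs$ref, vs$alt)
  vq <- vs[qual, , drop = FALSE]

  unknown <- setdiff(unique(vq$chrom), genome$chrom)
  if (length(unknown) > 0)
    stop("variants on chromosomes absent from the genome table: ",
         paste(unknown, collapse = ", "))

  tracks <- lapply(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    len <- genome$length[i]
    nbins <- ceiling(len / bin_size)
    v <- vq[vq$chrom == chrom, , drop = FALSE]
    if (any(v$pos > len))
      stop("variant beyond declared chromosome length: ", chrom, ":",
           format(max(v$pos), scientific = FALSE))
    idx <- floor((v$pos - 1) / bin_size)
    counts <- tabulate(idx + 1, nbins)
    tibble::tibble(chrom = chrom, bin_index = seq_len(nbins) - 1,
                   bin_start = (seq_len(nbins) - 1) * bin_size + 1,
                   bin_end = pmin(seq_len(nbins) * bin_size, len),
                   count = counts)
  })
  out <- dplyr::bind_rows(tracks)
  attr(out, "bin_size") <- bin_size
  class(out) <- unique(c("bin_track", class(out)))
  out
}

#' Call the mapping interval from binned variant counts
#'
#' Formalizes "where variant frequency returns to background levels": the
#' background level is the genome-wide median bin count and an interval is
#' a maximal run of contiguous bins whose counts all exceed it, i.e. the
#' interval ends where counts return to the background. A run is only
#' reported when its peak count exceeds `background + k_mad * MAD` (median
#' absolute deviation scaled by 1.4826 for consistency with the median,
#' floored at one count so the threshold stays meaningful when most bins
#' are empty). The run containing the genome-wide maximum bin is the
#' primary interval; any other reported run is a secondary peak, with its
#' width, mirroring the narrow, sharp-edged telomeric artifact peaks that
#' reference-stock differences produce and that peak shape discounts.
#'
#' @param bins A `bin_track` from [bin_variants()].
#' @param k_mad Threshold multiplier (default 5).
#' @return A tibble with columns `chrom`, `start`, `end` (bp, 1-based
#'   inclusive, on bin boundaries), `peak_bin` (0-based index of the run's
#'   maximum), `peak_count`, `background_level`, `threshold`, `width_bins`,
#'   `primary`. Zero rows (with a message) when no bin exceeds the
#'   threshold.
#' @export
call_interval <- function(bins, k_mad = 5) {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), peak_bin = integer(),
                          peak_count = integer(), background_level = numeric(),
                          threshold = numeric(), width_bins = integer(),
                          primary = logical())
  background <- median(bins$count)
  mad_val <- max(mad(bins$count), 1)
  threshold <- background + k_mad * mad_val

  if (!any(bins$count > threshold)) {
    message("no bin exceeds the peak threshold (", signif(threshold, 4),
            "); no interval called")
    return(empty)
  }
  global_max <- which.max(bins$count)

  out <- list()
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom, , drop = FALSE]
    r <- rle(b$count > background)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      rows <- starts[j]:ends[j]
      if (max(b$count[rows]) <= threshold) next  # never left the noise
      peak_row <- rows[which.max(b$count[rows])]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chrom,
        start = b$bin_start[rows[1]],
        end = b$bin_end[rows[length(rows)]],
        peak_bin = b$bin_index[peak_row],
        peak_count = b$count[peak_row],
        background_level = background,
        threshold = threshold,
        width_bins = length(rows),
        primary = chrom == bins$chrom[global_max] &&
          bins$bin_index[global_max] %in% b$bin_index[rows])
    }
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, dplyr::desc(.data$primary), dplyr::desc(.data$peak_count))
}

#' Plot binned homozygous-variant counts
#'
#' One panel per chromosome, count against bin midpoint, with called
#' intervals shaded when supplied.
#'
#' @param bins A `bin_track`.
#' @param intervals Optional result of [call_interval()].
#' @return A ggplot object.
#' @export
plot_bin_track <- function(bins, intervals = NULL) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(
    x = (.data$bin_start + .data$bin_end) / 2e6, y = .data$count)) +
    ggplot2::geom_col(width = attr(bins, "bin_size") / 1e6,
                      fill = "grey30") +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "Position (Mbp)",
                  y = "Homozygous variants per bin") +
    ggplot2::theme_bw()
  if (!is.null(intervals) && nrow(intervals) > 0) {
    p <- p + ggplot2::geom_rect(
      data = intervals,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf, fill = .data$primary),
      alpha = 0.2, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "steelblue"),
                                 guide = "none")
  }
  p
}

#' Write a bin track as TSV
#'
#' Columns: chrom, bin_start (1-based), bin_end, count.
#'
#' @param bins A `bin_track`.
#' @param path Output path.
#' @export
write_bins_tsv <- function(bins, path) {
  .write_tsv(as.data.frame(bins)[, c("chrom", "bin_start", "bin_end",
                                     "count")], path)
}
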