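#' Aggregate a fine raster to a coarser grid by area-weighted mean
#'
#' Each target cell receives the area-weighted mean of the source cells it
#' overlaps, ignoring missing source cells; a target cell whose footprint is
#' entirely missing becomes `NA`. ET is an intensive depth variable, so the
#' area-weighted mean is the aggregation that conserves the spatial mean.
#'
#' @param raster Source [et_raster()] (single- or multi-band).
#' @param target Target [et_grid()]; its pixel size must be >= the source's.
#' @return An [et_raster()] on `target`.
#' @export
resample_mean <- function(raster, target) {
  src <- raster$grid
  if (target$pixel_size < src$pixel_size)
    stop("target grid is finer than the source; resample_mean only aggregates")

  # Separable 1-D overlaps: cell edges along x and y for both grids.
  ov <- function(t0, tsz, tn, s0, ssz, sn, descending = FALSE) {
    # returns, for each target index, the source indices and overlap lengths
    lapply(seq_len(tn), function(ti) {
      if (descending) {
        hi <- t0 - (ti - 1L) * tsz; lo <- hi - tsz
        s_hi <- s0 - (seq_len(sn) - 1L) * ssz; s_lo <- s_hi - ssz
        w <- pmax(0, pmin(hi, s_hi) - pmax(lo, s_lo))
      } else {
        lo <- t0 + (ti - 1L) * tsz; hi <- lo + tsz
        s_lo <- s0 + (seq_len(sn) - 1L) * ssz; s_hi <- s_lo + ssz
        w <- pmax(0, pmin(hi, s_hi) - pmax(lo, s_lo))
      }
      idx <- which(w > 0)
      list(idx = idx, w = w[idx])
    })
  }
  col_ov <- ov(target$origin_x, target$pixel_size, target$n_cols,
               src$origin_x, src$pixel_size, src$n_cols)
  row_ov <- ov(target$origin_y, target$pixel_size, target$n_rows,
               src$origin_y, src$pixel_size, src$n_rows, descending = TRUE)

  nb <- n_bands(raster)
  out <- array(NA_real_, dim = c(target$n_rows, target$n_cols, nb))
  for (b in seq_len(nb)) {
    m <- raster_band(raster, b)
    for (tr in seq_len(target$n_rows)) {
      ro <- row_ov[[tr]]
      if (length(ro$idx) == 0L) next
      for (tc in seq_len(target$n_cols)) {
        co <- col_ov[[tc]]
        if (length(co$idx) == 0L) next
        sub <- m[ro$idx, co$idx, drop = FALSE]
        w <- outer(ro$w, co$w)
        ok <- !is.na(sub)
        if (!any(ok)) next
        out[tr, tc, b] <- sum(w[ok] * sub[ok]) / sum(w[ok])
      }
    }
  }
  vals <- if (nb == 1L)
    matrix(out[, , 1L], target$n_rows, target$n_cols) else out
  et_raster(vals, target, band_names = raster$band_names)
}
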