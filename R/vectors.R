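# Noise-vector rejection by neighbor similarity, and summary statistics.

#' Filter noise vectors by neighbor similarity
#'
#' Because adjacent ROIs overlap heavily, genuine flow vectors agree with
#' their grid neighbors in direction and magnitude while noise vectors do
#' not. A vector is retained iff it passed the fitting criteria and at
#' least `min_agreeing_neighbors` of its (up to 8) same-TOI grid neighbors
#' agree: angular difference within `max_angle_deg` and magnitude ratio
#' within `magnitude_ratio_bounds`.
#'
#' @param field a `vector_field` data.frame (needs `ix`, `iy`, `toi`,
#'   `vx`, `vy`, `magnitude`, `direction`, `valid`).
#' @param similarity list with `max_angle_deg`, `magnitude_ratio_bounds`,
#'   `min_agreeing_neighbors`.
#' @return The field with its `retained` column (re)computed.
#' @export
filter_noise_vectors <- function(field,
                                 similarity = list(max_angle_deg = 45,
                                                   magnitude_ratio_bounds = c(0.5, 2),
                                                   min_agreeing_neighbors = 3)) {
  n <- nrow(field)
  retained <- logical(n)
  if (n == 0) {
    field$retained <- retained
    return(field)
  }
  max_ang <- similarity$max_angle_deg * pi / 180
  rb <- similarity$magnitude_ratio_bounds
  need <- similarity$min_agreeing_neighbors
  valid_idx <- which(field$valid)
  key <- paste(field$ix, field$iy, field$toi, sep = "_")
  lookup <- split(seq_len(n), key)
  for (i in valid_idx) {
    agree <- 0L
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      k <- sprintf("%d_%d_%d", field$ix[i] + dx, field$iy[i] + dy,
                   field$toi[i])
      js <- lookup[[k]]
      if (is.null(js)) next
      for (j in js) {
        if (!field$valid[j]) next
        dang <- abs(field$direction[i] - field$direction[j])
        dang <- min(dang, 2 * pi - dang)
        mi <- field$magnitude[i]; mj <- field$magnitude[j]
        ratio_ok <- if (mi == 0 && mj == 0) TRUE
        else if (mi == 0 || mj == 0) FALSE
        else {
          rr <- mj / mi
          rr >= rb[1] && rr <= rb[2]
        }
        if (dang <= max_ang && ratio_ok) agree <- agree + 1L
      }
    }
    retained[i] <- agree >= need
  }
  field$retained <- retained
  field
}

#' Mean retained-vector speed
#'
#' @param field a `vector_field` with a `retained` column.
#' @return Mean magnitude (um/min) over retained vectors.
#' @export
mean_velocity <- function(field) {
  if (!any(field$retained)) stop("no retained vectors")
  mean(field$magnitude[field$retained])
}
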