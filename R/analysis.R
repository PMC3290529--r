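#' Region specification
#'
#' Pixel index sets used for response averaging.  The figure (centre) region
#' is the central `fig_size` x `fig_size` block; the ground (surround) region
#' is everything else; together they tile the grid with no border buffer.
#'
#' @param N grid side.
#' @param fig_size side of the central square.
#' @param region `"figure"`/`"centre"` or `"ground"`/`"surround"`.
#' @return An object of class `region_spec` holding the (row, col) logical
#'   mask and the region size.
#' @export
region_spec <- function(N, fig_size, region = c("figure", "ground", "centre", "surround")) {
  region <- match.arg(region)
  canonical <- if (region %in% c("figure", "centre")) "figure" else "ground"
  f <- unclass(make_fg_texture(N, fig_size)$feat1) == 1
  mask <- if (canonical == "figure") f else !f
  structure(list(label = canonical, mask = mask, N = as.integer(N),
                 size = sum(mask)),
            class = "region_spec")
}

#' Mean per-neuron spike count in a region and time window
#'
#' Total spikes of the region's neurons inside the half-open window, divided
#' by the region size, and additionally by the number of channels when
#' averaging over channels (the convention for figure/ground responses:
#' centre and surround responses of both feature channels are averaged).
#'
#' @param raster a `spike_raster` from [run_network()].
#' @param region a [region_spec()].
#' @param window numeric length-2, `[t0, t1)` in ms.
#' @param layer layer to read (1 or 2).
#' @param channels channel indices to average over.
#' @return Mean per-neuron spike count (a single number).
#' @export
count_spikes <- function(raster, region, window, layer = 2, channels = NULL) {
  stopifnot(inherits(raster, "spike_raster"), inherits(region, "region_spec"),
            length(window) == 2)
  if (window[2] <= window[1]) stop("window must satisfy t0 < t1")
  if (region$size == 0) stop("empty region")
  if (is.null(channels)) channels <- seq_len(attr(raster, "n_channels"))
  sel <- raster$layer == layer & raster$channel %in% channels &
    raster$t_ms >= window[1] & raster$t_ms < window[2]
  if (!any(sel)) return(0)
  r <- raster[sel, , drop = FALSE]
  inreg <- region$mask[cbind(r$row, r$col)]
  sum(inreg) / region$size / length(channels)
}

#' Convert a windowed spike count to a firing rate
#'
#' @param count mean per-neuron spike count in the window.
#' @param window numeric length-2 window (ms) or a single window length (ms).
#' @return Firing rate in spikes/sec: `count * 1000 / window_ms`.
#' @examples
#' firing_rate(12, c(0, 50))  # 240
#' @export
firing_rate <- function(count, window) {
  len <- if (length(window) == 2) diff(window) else window
  if (len <= 0) stop("window length must be positive")
  count * 1000 / len
}

#' Figure-ground modulation index
#'
#' The raw difference `F - G` between the per-neuron spike counts at the
#' figure and ground regions (both channel-averaged, conventionally over the
#' first 50 ms).  Antisymmetric: swapping the arguments flips the sign.
#'
#' @param F figure (centre) per-neuron spike count.
#' @param G ground (surround) per-neuron spike count.
#' @return `F - G`.
#' @export
modulation_index <- function(F, G) {
  stopifnot(all(F >= 0), all(G >= 0))
  F - G
}

#' Percent-suppression curve with dip detection
#'
#' Converts per-condition masked responses into percentage suppression
#' relative to an unmasked control, `100 * (1 - masked / control)`, and
#' locates the dips: local maxima of suppression (equivalently local minima
#' of the response), reported with ties broken toward the smaller SOA.
#'
#' @param soa vector of stimulus-onset asynchronies (ms), sorted ascending.
#' @param masked masked response per SOA (same length as `soa`).
#' @param control unmasked control response (positive scalar).
#' @return A data.frame with columns `soa`, `masked`, `suppression`, plus
#'   attribute `dips`: a data.frame of dip SOAs and suppression values.
#' @export
suppression_curve <- function(soa, masked, control) {
  stopifnot(length(soa) == length(masked), length(control) == 1)
  if (control <= 0) stop("control response must be positive")
  if (is.unsorted(soa)) {
    o <- order(soa)
    soa <- soa[o]
    masked <- masked[o]
  }
  supp <- 100 * (1 - masked / control)
  n <- length(supp)
  is_dip <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) supp[i - 1] else -Inf
    right <- if (i < n) supp[i + 1] else -Inf
    # strict on the left, non-strict on the right: a plateau's smallest SOA wins
    is_dip[i] <- supp[i] > left && supp[i] >= right && supp[i] > 0
  }
  out <- data.frame(soa = soa, masked = masked, suppression = supp)
  attr(out, "dips") <- data.frame(soa = soa[is_dip],
                                  suppression = supp[is_dip])
  out
}

#' Response summary
#'
#' Bundles a windowed per-neuron count with its window and the implied rate.
#'
#' @param count mean per-neuron spike count.
#' @param window half-open window in ms.
#' @return An object of class `response_summary`.
#' @export
response_summary <- function(count, window) {
  stopifnot(count >= 0, length(window) == 2, window[2] > window[1])
  structure(list(count = count, window = window,
                 rate = firing_rate(count, window)),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("%.3f spikes/neuron in [%g, %g) ms = %.1f spikes/sec\n",
              x$count, x$window[1], x$window[2], x$rate))
  invisible(x)
}
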