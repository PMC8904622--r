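#' Standard 64-channel EEG montage with frontal flags
#'
#' Returns the 10-10 montage used throughout the package: 64 unique channel
#' names with approximate 2-D scalp coordinates (x: left -1 to right +1,
#' y: posterior -1 to anterior +1) and a flag marking the 16 frontal
#' channels (Fp1, Fp2, AF7, AF3, AFz, AF4, AF8, F7, F5, F3, F1, Fz, F2, F4,
#' F6, F8) that the robustness re-analysis excludes.
#'
#' @return A data frame with columns `name`, `x`, `y`, `is_frontal`.
#' @export
channel_layout <- function() {
  rows <- list(
    # name prefix, y coordinate, channel names left-to-right
    list("Fp",  0.95, c("Fp1", "Fp2")),
    list("AF",  0.80, c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list("F",   0.60, c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list("FT9", 0.35, c("FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4",
                        "FC6", "FT8", "FT10")),
    list("C",   0.00, c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    list("TP",  -0.35, c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2",
                         "CP4", "CP6", "TP8", "TP10")),
    list("P",   -0.60, c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    list("PO",  -0.80, c("PO7", "PO3", "POz", "PO4", "PO8")),
    list("O",   -0.95, c("O1", "Oz", "O2")),
    list("Iz",  -1.00, "Iz")
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    nm <- r[[3]]
    k <- length(nm)
    x <- if (k == 1) 0 else seq(-1, 1, length.out = k)
    data.frame(name = nm, x = x, y = r[[2]], stringsAsFactors = FALSE)
  }))
  frontal <- c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
               "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")
  out$is_frontal <- out$name %in% frontal
  stopifnot(nrow(out) == 64L, !anyDuplicated(out$name),
            sum(out$is_frontal) == 16L)
  rownames(out) <- NULL
  out
}

#' Drop frontal channels from a layout or band-power tensor
#'
#' Removes the 16 frontal channels so all downstream operations (electrode
#' weighting, aggregation, slope, projection) can be re-run as a robustness
#' check against ocular contamination of high-frequency power.
#'
#' @param x A layout data frame from [channel_layout()], or a
#'   `band_power_tensor` (see [generate_power()]).
#' @param layout The layout matching `x`'s channel axis (tensor input only).
#' @return The input with frontal channels removed.
#' @export
exclude_frontal <- function(x, layout = channel_layout()) {
  if (is.data.frame(x)) {
    if (is.null(x$is_frontal)) stop("layout has no 'is_frontal' flags")
    return(x[!x$is_frontal, , drop = FALSE])
  }
  if (inherits(x, "band_power_tensor")) {
    ch <- dimnames(x)[[3]]
    if (is.null(ch)) stop("tensor has no channel names")
    unknown <- setdiff(ch, layout$name)
    if (length(unknown))
      stop("unknown channel names: ", paste(unknown, collapse = ", "))
    keep <- !(ch %in% layout$name[layout$is_frontal])
    out <- x[, , keep, , drop = FALSE]
    for (a in setdiff(names(attributes(x)), c("dim", "dimnames")))
      attr(out, a) <- attr(x, a)
    return(out)
  }
  stop("x must be a layout data frame or a band_power_tensor")
}
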