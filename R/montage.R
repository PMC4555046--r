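#' Default 64-channel EEG montage
#'
#' Builds a 64-channel 10-10-style electrode layout with 2-D scalp
#' coordinates (x: left negative / right positive, y: anterior positive /
#' posterior negative) and a neighbourhood annotation for the hand-area
#' electrodes C3 and C4. The neighbourhood is what defines the classic
#' mu/beta feature-channel set (C3 plus its 8 surrounding electrodes for
#' right-hand movements).
#'
#' @param n_channels Number of channels to return (the first `n_channels`
#'   of the 64-channel layout; at least 16 so the motor strip is present).
#' @return A data.frame with columns `label`, `x`, `y` and an attribute
#'   `neighbors`, a named list mapping electrode labels to their annotated
#'   neighbour labels.
#' @export
default_montage <- function(n_channels = 64) {
  stopifnot(is.numeric(n_channels), n_channels >= 16, n_channels <= 64)
  rows <- list(
    # label prefix, y, column labels (left to right)
    list("Fp", 0.90, c("1", "z", "2")),
    list("AF", 0.75, c("7", "3", "z", "4", "8")),
    list("F",  0.60, c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list("FC", 0.30, c("5", "3", "1", "z", "2", "4", "6")),
    list("C",  0.00, c("5", "3", "1", "z", "2", "4", "6")),
    list("CP", -0.30, c("5", "3", "1", "z", "2", "4", "6")),
    list("P",  -0.60, c("7", "5", "3", "1", "z", "2", "4", "6", "8")),
    list("PO", -0.75, c("7", "3", "z", "4", "8")),
    list("O",  -0.90, c("1", "z", "2"))
  )
  colx <- c("z" = 0, "1" = 0.15, "2" = 0.15, "3" = 0.45, "4" = 0.45,
            "5" = 0.75, "6" = 0.75, "7" = 1.00, "8" = 1.00, "9" = 1.15,
            "10" = 1.15)
  lab <- character(0); xs <- numeric(0); ys <- numeric(0)
  for (r in rows) {
    for (cl in r[[3]]) {
      lab <- c(lab, paste0(r[[1]], cl))
      sgn <- if (cl == "z") 0 else if (as.integer(cl) %% 2 == 1) -1 else 1
      xs <- c(xs, sgn * colx[[cl]])
      ys <- c(ys, r[[2]])
    }
  }
  extra <- data.frame(
    label = c("T7", "T8", "FT7", "FT8", "TP7", "TP8", "P9", "P10", "Iz"),
    x = c(-1.15, 1.15, -1.1, 1.1, -1.1, 1.1, -1.15, 1.15, 0),
    y = c(0, 0, 0.3, 0.3, -0.3, -0.3, -0.6, -0.6, -1.0),
    stringsAsFactors = FALSE
  )
  mon <- rbind(data.frame(label = lab, x = xs, y = ys,
                          stringsAsFactors = FALSE), extra)
  stopifnot(nrow(mon) == 64, !anyDuplicated(mon$label))
  mon <- mon[seq_len(n_channels), , drop = FALSE]
  rownames(mon) <- NULL
  nb <- list(
    C3 = c("FC5", "FC3", "FC1", "C5", "C1", "CP5", "CP3", "CP1"),
    C4 = c("FC2", "FC4", "FC6", "C2", "C6", "CP2", "CP4", "CP6")
  )
  nb <- lapply(nb, function(v) v[v %in% mon$label])
  nb <- nb[names(nb) %in% mon$label]
  attr(mon, "neighbors") <- nb
  class(mon) <- c("eeg_montage", "data.frame")
  mon
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels; neighbour annotations: %s\n",
              nrow(x), paste(names(attr(x, "neighbors")), collapse = ", ")))
  invisible(x)
}
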