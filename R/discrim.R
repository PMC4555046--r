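#' Point-biserial r and r-squared between two condition samples
#'
#' Computes \eqn{r = \frac{\sqrt{n_1 n_2}}{n_1 + n_2} \cdot
#' \frac{\mathrm{mean}(w_1) - \mathrm{mean}(w_2)}{\mathrm{std}(w_1 \cup w_2)}}
#' with the *population* standard deviation of the pooled sample (divide by
#' \eqn{n_1 + n_2}). With that convention r is exactly the Pearson
#' correlation between the pooled values and a binary group indicator
#' (the point-biserial correlation), and r-squared the usual coefficient
#' of determination for a binary contrast.
#'
#' @param w1,w2 Numeric feature vectors of the two conditions.
#' @return A list with elements `r` and `r2`.
#' @export
r_squared <- function(w1, w2) {
  n1 <- length(w1); n2 <- length(w2)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(w1, w2)
  sd_pop <- sqrt(mean((pooled - mean(pooled))^2))
  if (sd_pop == 0) stop("zero pooled variance: r is undefined", call. = FALSE)
  r <- sqrt(n1 * n2) / (n1 + n2) * (mean(w1) - mean(w2)) / sd_pop
  list(r = r, r2 = r * r)
}

feature_channel_values <- function(features, k_or_band) {
  if (inherits(features, "projection_table")) {
    k <- as.integer(sub("^PC", "", k_or_band))
    if (is.na(k) || k < 1 || k > features$K)
      stop(sprintf("unknown component '%s'", k_or_band), call. = FALSE)
    features$weights[, , k, drop = TRUE]
  } else if (inherits(features, "band_power_table")) {
    if (!identical(k_or_band, features$band))
      stop(sprintf("table holds band '%s', not '%s'", features$band, k_or_band),
           call. = FALSE)
    features$values
  } else {
    stop("features must be a projection_table or band_power_table", call. = FALSE)
  }
}

#' Channel-wise r-squared topography for a condition pair
#'
#' Applies [r_squared()] per channel to one feature's per-segment values
#' split by the two conditions, producing a scalp map of discriminability.
#'
#' @param features A `projection_table` or `band_power_table`.
#' @param labels Per-segment condition labels (defaults to the table's own).
#' @param pair Length-2 character vector `(condA, condB)`; for the
#'   detection contrast use `"movement"` to pool all non-rest segments.
#' @param k_or_band Which feature: `"PC1"`.. for projection tables, the
#'   band name for band-power tables.
#' @return An `rsq_map`: data.frame with columns `channel`, `x`, `y`, `r`,
#'   `r2`, plus attributes `pair` and `feature`.
#' @export
rsq_topography <- function(features, labels = features$labels, pair, k_or_band) {
  vals <- feature_channel_values(features, k_or_band)
  grp <- label_group(labels, pair)
  if (!any(grp == 1L)) stop(sprintf("condition '%s' absent", pair[1]), call. = FALSE)
  if (!any(grp == 2L)) stop(sprintf("condition '%s' absent", pair[2]), call. = FALSE)
  n <- ncol(vals)
  r <- numeric(n); r2 <- numeric(n)
  for (ch in seq_len(n)) {
    res <- r_squared(vals[grp == 1L, ch], vals[grp == 2L, ch])
    r[ch] <- res$r; r2[ch] <- res$r2
  }
  mon <- features$montage
  out <- data.frame(channel = features$channel_labels,
                    x = mon$x[match(features$channel_labels, mon$label)],
                    y = mon$y[match(features$channel_labels, mon$label)],
                    r = r, r2 = r2, stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  attr(out, "feature") <- k_or_band
  class(out) <- c("rsq_map", "data.frame")
  out
}

# Map labels onto groups 1/2 for a condition pair; "movement" pools all
# non-rest labels.
label_group <- function(labels, pair) {
  grp <- integer(length(labels))
  for (g in 1:2) {
    if (identical(pair[g], "movement")) grp[labels != "rest"] <- g
    else grp[labels == pair[g]] <- g
  }
  grp
}

#' Select top feature channels from r-squared maps
#'
#' Ranks channels within each map by descending r-squared (ties broken
#' stably by channel index) and keeps the first `top_n`; the returned
#' selection is the union across maps (condition pairs and/or features),
#' ordered by channel index for determinism.
#'
#' @param maps A single `rsq_map` or a list of them.
#' @param top_n Channels kept per map (default 10); more than the number
#'   of channels selects all.
#' @return A `channel_selection`: list with `channels` (labels) and
#'   `provenance` (data.frame of map feature/pair and its top channels).
#' @export
select_channels <- function(maps, top_n = 10) {
  if (inherits(maps, "rsq_map")) maps <- list(maps)
  if (length(maps) == 0) stop("no r-squared maps supplied", call. = FALSE)
  all_labels <- maps[[1]]$channel
  chosen <- character(0)
  prov <- list()
  for (i in seq_along(maps)) {
    mp <- maps[[i]]
    ord <- order(-mp$r2, seq_len(nrow(mp)))     # stable: ties by channel index
    top <- mp$channel[ord[seq_len(min(top_n, nrow(mp)))]]
    chosen <- union(chosen, top)
    prov[[i]] <- data.frame(
      feature = attr(mp, "feature") %||% NA_character_,
      pair = paste(attr(mp, "pair"), collapse = " vs "),
      channels = paste(top, collapse = ","),
      stringsAsFactors = FALSE)
  }
  chosen <- all_labels[sort(match(chosen, all_labels))]
  structure(list(channels = chosen, provenance = do.call(rbind, prov)),
            class = "channel_selection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classic mu/beta feature channels: C3 (or C4) and neighbours
#'
#' Returns the hand-area electrode contralateral to the moving hand plus
#' its annotated neighbours -- the conventional feature-channel set for
#' mu/beta band-power features (C3 and its 8 neighbours for right-hand
#' movements).
#'
#' @param montage A montage with a `neighbors` attribute (see
#'   [default_montage()]).
#' @param hand `"right"` (maps to left-hemisphere C3) or `"left"` (C4).
#' @return A `channel_selection`.
#' @export
mu_beta_channels <- function(montage, hand = c("right", "left")) {
  hand <- match.arg(hand)
  center <- if (hand == "right") "C3" else "C4"
  if (!(center %in% montage$label))
    stop(sprintf("montage lacks channel %s", center), call. = FALSE)
  nb <- attr(montage, "neighbors")
  if (is.null(nb) || is.null(nb[[center]]))
    stop(sprintf("montage has no neighbour annotation for %s", center),
         call. = FALSE)
  structure(list(channels = c(center, nb[[center]]),
                 provenance = data.frame(feature = "mu/beta",
                                         pair = sprintf("%s + neighbours", center),
                                         channels = paste(c(center, nb[[center]]),
                                                          collapse = ","),
                                         stringsAsFactors = FALSE)),
            class = "channel_selection")
}

#' Export a topography as CSV
#'
#' Writes per-channel values with montage coordinates
#' (`channel,x,y,value` columns) for consumption by any scalp-plotting
#' tool.
#'
#' @param map An `rsq_map` (uses the `r2` column) or a data.frame with
#'   columns `channel`, `x`, `y` and one value column.
#' @param path Output CSV path.
#' @param value Which column to export as `value`.
#' @return `path`, invisibly.
#' @export
write_topography_csv <- function(map, path, value = "r2") {
  df <- data.frame(channel = map$channel, x = map$x, y = map$y,
                   value = map[[value]], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
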