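#' Concentration-response survival data
#'
#' Container for one toxicity experiment (one observation day): per tested
#' concentration, the number of exposed animals and the number surviving.
#' Duplicate rows for the same concentration (and day) are aggregated by
#' summing counts, mirroring designs where animals are kept individually.
#'
#' @param concentration toxicant concentration in ug/L, `>= 0`; must include
#'   a control (concentration 0).
#' @param n_exposed number of animals exposed per row, `> 0`.
#' @param n_surviving number surviving, `0 <= n_surviving <= n_exposed`.
#' @param day optional integer observation day.
#' @param label optional treatment label.
#' @return A data.frame of class `conc_response` with one row per
#'   concentration (per day), sorted by day then concentration, and a
#'   `survival` column (`n_surviving / n_exposed`).
#' @export
conc_response <- function(concentration, n_exposed, n_surviving,
                          day = NULL, label = NULL) {
  n <- length(concentration)
  if (length(n_exposed) != n || length(n_surviving) != n) {
    stop("'concentration', 'n_exposed' and 'n_surviving' lengths differ",
         call. = FALSE)
  }
  df <- data.frame(
    concentration = as.numeric(concentration),
    n_exposed = as.numeric(n_exposed),
    n_surviving = as.numeric(n_surviving),
    day = if (is.null(day)) NA_integer_ else as.integer(day),
    label = if (is.null(label)) NA_character_ else as.character(label),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(df$concentration) | df$concentration < 0 |
                 df$n_exposed <= 0 | df$n_surviving < 0 |
                 df$n_surviving > df$n_exposed |
                 df$n_exposed != round(df$n_exposed) |
                 df$n_surviving != round(df$n_surviving))
  if (length(bad)) {
    stop("invalid rows (need concentration >= 0 and integer counts with ",
         "0 <= n_surviving <= n_exposed): rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$day, df$concentration)
  agg <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(concentration = g$concentration[1],
               n_exposed = sum(g$n_exposed),
               n_surviving = sum(g$n_surviving),
               day = g$day[1], label = g$label[1],
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$day, agg$concentration), , drop = FALSE]
  rownames(agg) <- NULL
  agg$survival <- agg$n_surviving / agg$n_exposed
  for (d in unique(agg$day)) {
    sub <- agg[is.na(agg$day) == is.na(d) & (is.na(d) | agg$day %in% d), ]
    if (!any(sub$concentration == 0)) {
      stop("missing control: no row with concentration 0",
           if (!is.na(d)) sprintf(" for day %d", d) else "", call. = FALSE)
    }
  }
  class(agg) <- c("conc_response", class(agg))
  agg
}

#' @export
print.conc_response <- function(x, ...) {
  cat(sprintf("Concentration-response data: %d concentrations, %d animals\n",
              nrow(x), sum(x$n_exposed)))
  print(as.data.frame(x), ...)
  invisible(x)
}

# restrict a conc_response to a single observation day (NA day = unspecified)
conc_response_day <- function(data, day = NULL) {
  stopifnot(inherits(data, "conc_response"))
  days <- unique(data$day)
  if (is.null(day)) {
    if (length(days) > 1L) {
      stop("data contain several observation days (",
           paste(days, collapse = ", "),
           "); select one with 'day ='", call. = FALSE)
    }
    return(data)
  }
  sel <- if (is.na(day)) is.na(data$day) else !is.na(data$day) & data$day == day
  if (!any(sel)) stop("no rows for day ", day, call. = FALSE)
  out <- data[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
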