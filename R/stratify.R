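#' RadScore stratification groups
#'
#' Assigns patients to RadScore-low / median / high groups using boundaries
#' fitted on the *training* scores only. The default is tertile boundaries
#' (33.3 / 66.7 percentiles, three groups); `mode = "quartile"` uses the
#' training quartiles with the middle two quarters merged into the median
#' group. Assignment uses half-open intervals `[low, b1), [b1, b2),
#' [b2, high]`: a value exactly on a boundary goes to the upper group.
#' All-equal training scores collapse to a single degenerate group, with a
#' warning.
#'
#' @param radscores scores of the patients to stratify.
#' @param train_scores scores used to fit the boundaries (defaults to
#'   `radscores`; supply the training scores when stratifying a test set).
#' @param mode `"tertile"` (default) or `"quartile"`.
#' @return An object of class `stratification_result`: a list with
#'   `boundaries` and an `assignment` tibble (`radscore`, `group` ordered
#'   factor low < median < high).
#' @export
stratify <- function(radscores, train_scores = radscores,
                     mode = c("tertile", "quartile")) {
  mode <- match.arg(mode)
  probs <- if (mode == "tertile") c(1, 2) / 3 else c(0.25, 0.75)
  b <- stats::quantile(train_scores, probs, names = FALSE, type = 7)
  lev <- c("RadScore-low", "RadScore-median", "RadScore-high")
  if (b[1] == b[2]) {
    warn("degenerate boundaries (all training scores equal): single group")
  }
  grp <- ifelse(radscores < b[1], lev[1],
                ifelse(radscores < b[2], lev[2], lev[3]))
  structure(
    list(
      boundaries = b,
      mode = mode,
      assignment = tibble(radscore = radscores,
                          group = factor(grp, levels = lev, ordered = TRUE))
    ),
    class = "stratification_result"
  )
}

#' Per-group label positivity rates
#'
#' @param result a [stratify()] result.
#' @param labels data frame of binary label columns (one row per stratified
#'   patient).
#' @return a tibble with `group`, `label`, `n`, `positives`, `rate`,
#'   `percent`. Rates aggregated over groups reproduce the cohort
#'   prevalence exactly.
#' @export
group_rates <- function(result, labels) {
  stopifnot(inherits(result, "stratification_result"))
  labels <- as_tibble(labels)
  labels <- labels[, setdiff(names(labels), "patient_id"), drop = FALSE]
  if (ncol(labels) == 0L) abort("no label columns supplied")
  if (nrow(labels) != nrow(result$assignment)) {
    abort("labels must have one row per stratified patient")
  }
  bad <- names(labels)[vapply(labels, function(l) all(is.na(l)) ||
                                !all(l %in% c(0, 1, NA)), TRUE)]
  if (length(bad)) {
    abort(sprintf("label column(s) not binary or empty: %s",
                  paste(bad, collapse = ", ")))
  }
  df <- dplyr::bind_cols(result$assignment["group"], labels)
  tidyr::pivot_longer(df, -"group", names_to = "label",
                      values_to = "positive") %>%
    group_by(.data$group, .data$label) %>%
    summarise(n = dplyr::n(), positives = sum(.data$positive),
              .groups = "drop") %>%
    mutate(rate = .data$positives / .data$n, percent = 100 * .data$rate)
}

#' Spearman rank correlation with a binary label
#'
#' Midrank-tie Spearman's rho; p-value from the t approximation, or exact
#' (enumeration over label arrangements) when n <= 9.
#'
#' @param radscores numeric scores.
#' @param label binary (0/1) vector, same length.
#' @return a list with `rho` and `p`.
#' @export
spearman_rho <- function(radscores, label) {
  n <- length(radscores)
  if (n != length(label)) abort("lengths differ")
  rx <- rank(radscores)
  ry <- rank(label)
  if (sd(rx) == 0 || sd(ry) == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rx, ry)
  if (n <= 9L && all(label %in% c(0, 1))) {
    npos <- sum(label == 1)
    combos <- utils::combn(n, npos)
    null_rho <- apply(combos, 2, function(ix) {
      yy <- rep(0, n)
      yy[ix] <- 1
      cor(rx, rank(yy))
    })
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' RadScore-vs-label correlation matrix
#'
#' Spearman's rho (with raw and BH-adjusted p-values) between each
#' RadScore column and each therapy-response label, including the EGFR
#' wild-type indicator (1 - EGFR) when an `EGFR` column is present — the
#' data behind a correlation heatmap across therapy responses.
#'
#' @param radscores a data frame of score columns (e.g. per target or per
#'   region), or a single numeric vector.
#' @param labels data frame of binary label columns.
#' @return An object of class `correlation_matrix`: tibble with `score`,
#'   `label`, `rho`, `p`, `q_value`.
#' @export
correlation_heatmap_data <- function(radscores, labels) {
  if (is.numeric(radscores)) radscores <- tibble(RadScore = radscores)
  radscores <- as_tibble(radscores)
  labels <- as_tibble(labels)
  labels <- labels[, setdiff(names(labels), "patient_id"), drop = FALSE]
  if ("EGFR" %in% names(labels) && !("EGFR_wildtype" %in% names(labels))) {
    labels <- mutate(labels, EGFR_wildtype = 1L - .data$EGFR, .before = 1)
  }
  grid <- expand.grid(score = names(radscores), label = names(labels),
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(score, label) {
    sp <- spearman_rho(radscores[[score]], labels[[label]])
    tibble(score = score, label = label, rho = sp$rho, p = sp$p)
  })
  out <- dplyr::bind_rows(rows) %>%
    mutate(q_value = p.adjust(.data$p, method = "BH"))
  structure(out, class = c("correlation_matrix", class(tibble())))
}

#' @export
autoplot.correlation_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$label, y = .data$score,
                               fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$rho,
                      ifelse(.data$q_value < 0.05, "*", ""))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.stratification_result <- function(object, ...) {
  ggplot2::ggplot(object$assignment,
                  ggplot2::aes(x = .data$group, y = .data$radscore)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "RadScore") +
    ggplot2::theme_minimal()
}
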