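#' Extreme-group assignment from per-song speeds
#'
#' Sorts songs by mean normalized walking speed: the `n_group` fastest form
#' the activating group (a1 = fastest), the `n_group` slowest the relaxing
#' group (r1 = slowest), and `n_group` songs whose ranks are centered on the
#' median form the neutral group (ranks 22-31 of 52). Ties are broken
#' deterministically by stimulus id.
#'
#' @param speeds a [normalize_speeds()] table (columns `stimulus_id`, `v`).
#' @param n_group group size.
#' @return An object of class `group_assignment` with character vectors
#'   `activating` (ranked a1..), `relaxing` (ranked r1..) and `neutral`.
#' @export
extreme_groups <- function(speeds, n_group = 10) {
  if (nrow(speeds) < 3 * n_group) {
    stop("need at least ", 3 * n_group, " songs for three groups of ",
         n_group)
  }
  o <- order(speeds$v, speeds$stimulus_id)      # ascending speed
  ids <- speeds$stimulus_id[o]
  n <- length(ids)
  relaxing <- ids[seq_len(n_group)]             # r1 = slowest
  activating <- rev(ids[(n - n_group + 1):n])   # a1 = fastest
  start <- floor((n - n_group) / 2) + 1L
  neutral <- ids[start:(start + n_group - 1L)]
  structure(list(activating = activating, relaxing = relaxing,
                 neutral = neutral),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment>\n")
  cat(" activating:", paste(x$activating, collapse = " "), "\n")
  cat(" relaxing:  ", paste(x$relaxing, collapse = " "), "\n")
  cat(" neutral:   ", paste(x$neutral, collapse = " "), "\n")
  invisible(x)
}

# Closed-form Scheffe pairwise post-hoc test on a fitted one-way ANOVA.
scheffe_pairwise <- function(means, ns, mse, df_error, k) {
  pairs <- utils::combn(names(means), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    diff = NA_real_, F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    d <- means[g1] - means[g2]
    Fs <- d^2 / (mse * (1 / ns[g1] + 1 / ns[g2])) / (k - 1)
    out$diff[i] <- d
    out$F[i] <- Fs
    out$p[i] <- 1 - stats::pf(Fs, k - 1, df_error)
  }
  out
}

#' One-way ANOVA on group walking speeds with Scheffe post-hoc contrasts
#'
#' Compares the per-song mean normalized speeds of the activating, neutral
#' and relaxing groups by one-way ANOVA (via [stats::aov()]), followed by
#' pairwise Scheffe contrasts.
#'
#' @param speeds a [normalize_speeds()] table.
#' @param groups a [extreme_groups()] assignment.
#' @return List with `F`, `df` (length 2), `p`, `group_means`, `scheffe`
#'   (data frame of pairwise contrasts) and `degenerate` (TRUE when the
#'   within-group variance is zero).
#' @export
speed_anova <- function(speeds, groups) {
  v <- stats::setNames(speeds$v, speeds$stimulus_id)
  df <- data.frame(
    v = c(v[groups$activating], v[groups$neutral], v[groups$relaxing]),
    group = factor(rep(c("activating", "neutral", "relaxing"),
                       times = c(length(groups$activating),
                                 length(groups$neutral),
                                 length(groups$relaxing))))
  )
  fit <- stats::aov(v ~ group, data = df)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  means <- tapply(df$v, df$group, mean)
  ns <- tapply(df$v, df$group, length)
  k <- nlevels(df$group)
  list(F = tab[1, "F value"], df = c(tab[1, "Df"], tab["Residuals", "Df"]),
       p = tab[1, "Pr(>F)"], group_means = means,
       scheffe = scheffe_pairwise(means, ns, mse,
                                  tab["Residuals", "Df"], k),
       degenerate = isTRUE(mse == 0))
}

#' Per-feature t-tests between activating and relaxing songs
#'
#' Two-sample t-tests (Welch) of each selected sonic feature between the
#' activating and relaxing groups, with raw p-values as well as a
#' Holm-adjusted column.
#'
#' @param features matrix, songs as rows (rownames = stimulus ids), features
#'   as columns.
#' @param groups a [extreme_groups()] assignment.
#' @param feature_ids columns to test; all by default.
#' @return Data frame with columns `feature`, `t`, `p`, `p_holm`,
#'   `mean_activating`, `mean_relaxing`, `degenerate`.
#' @export
feature_ttests <- function(features, groups, feature_ids = NULL) {
  features <- as.matrix(features)
  if (is.null(feature_ids)) feature_ids <- colnames(features)
  a <- features[groups$activating, , drop = FALSE]
  r <- features[groups$relaxing, , drop = FALSE]
  rows <- lapply(feature_ids, function(f) {
    xa <- a[, f]; xr <- r[, f]
    degenerate <- stats::sd(xa) == 0 && stats::sd(xr) == 0
    if (degenerate) {
      data.frame(feature = f, t = 0, p = 1, mean_activating = mean(xa),
                 mean_relaxing = mean(xr), degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(xa, xr)
      data.frame(feature = f, t = unname(tt$statistic), p = tt$p.value,
                 mean_activating = mean(xa), mean_relaxing = mean(xr),
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out[, c("feature", "t", "p", "p_holm", "mean_activating",
          "mean_relaxing", "degenerate")]
}

#' Mann-Whitney tests on adjective ratings between extreme groups
#'
#' One Mann-Whitney U test per bipolar adjective pair on the mean ratings per
#' excerpt, activating versus relaxing group. Exact p-values are used when
#' there are no ties (the default [stats::wilcox.test()] behaviour); set
#' `exact = FALSE` for the normal approximation.
#'
#' @param ratings matrix, excerpts as rows (rownames = stimulus ids), nine
#'   adjective columns.
#' @param groups a [extreme_groups()] assignment.
#' @param exact logical passed to [stats::wilcox.test()].
#' @return Data frame with columns `adjective`, `U`, `U_prime`, `p`,
#'   `p_holm`, `tied`.
#' @export
ratings_tests <- function(ratings, groups, exact = NULL) {
  ratings <- as.matrix(ratings)
  a <- ratings[groups$activating, , drop = FALSE]
  r <- ratings[groups$relaxing, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(r)
  rows <- lapply(colnames(ratings), function(adj) {
    xa <- a[, adj]; xr <- r[, adj]
    tied <- anyDuplicated(c(xa, xr)) > 0
    wt <- suppressWarnings(stats::wilcox.test(xa, xr, exact = exact))
    U <- unname(wt$statistic)
    data.frame(adjective = adj, U = U, U_prime = n1 * n2 - U,
               p = wt$p.value, tied = tied, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out[, c("adjective", "U", "U_prime", "p", "p_holm", "tied")]
}

#' Bundled stimulus label fixture
#'
#' Loads the packaged 52-stimulus label table: stimulus ids 1-52 ordered from
#' most relaxing to most activating, with extreme-group rank labels r1..r10
#' (ids 1-10) and a10..a1 (ids 43-52); the 32 middle stimuli are unlabeled.
#'
#' @return Data frame with columns `song_id`, `label`, `group`.
#' @export
stimulus_labels <- function() {
  path <- system.file("extdata", "stimulus_labels.csv",
                      package = "walkbeat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
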