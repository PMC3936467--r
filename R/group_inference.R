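stat_map <- function(values, type, df, mask, grid, sign = NULL,
                     contrast = "") {
  structure(list(values = values, type = type, df = df, mask = mask,
                 grid = grid, sign = sign, contrast = contrast),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map [%s]: %s, df = %s, %d voxels in mask\n",
              x$contrast, x$type, paste(x$df, collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

#' One-sample t map
#'
#' Voxelwise `t = mean / (sd / sqrt(n))` with `df = n - 1` across subjects'
#' Fisher-z maps.  Voxels with zero between-subject variance are removed
#' from the analysis mask.
#'
#' @param z_maps n-by-V matrix of per-subject Fisher-z values (one row per
#'   subject, voxel order column-major on the grid).
#' @param mask logical analysis mask (3D array or voxel-length vector).
#' @param grid the [volume_grid()].
#' @return a `stat_map` with type `"t"`.
#' @export
one_sample_map <- function(z_maps, mask, grid) {
  n <- nrow(z_maps)
  if (is.null(n) || n < 2) stop("sample-size error: need n >= 2 maps")
  m <- as.vector(mask) != 0
  Y <- z_maps[, m, drop = FALSE]
  mu <- colMeans(Y)
  s <- sqrt(colSums(sweep(Y, 2, mu)^2) / (n - 1))
  tvals <- rep(NA_real_, ncol(z_maps))
  good <- s > 0
  tv <- rep(NA_real_, ncol(Y))
  tv[good] <- mu[good] / (s[good] / sqrt(n))
  tvals[m] <- tv
  newmask <- m
  newmask[m] <- good
  stat_map(tvals, "t", n - 1, newmask, grid, sign = sign(tvals),
           contrast = "one-sample")
}

#' Voxelwise two-group contrast (fixed-effects GLM)
#'
#' Fits `z ~ intercept + group (+ covariates)` by ordinary least squares at
#' every voxel and returns the F statistic for the group term with
#' df (1, n - k).  Direction is recorded as the sign of the adjusted group
#' difference (first group level minus second).
#'
#' @param z_maps n-by-V matrix of Fisher-z maps.
#' @param labels length-n factor (or character) with exactly 2 levels.
#' @param covariates optional data.frame/matrix of numeric covariates.
#' @param mask logical analysis mask.
#' @param grid the [volume_grid()].
#' @param contrast label stored in the result.
#' @return a `stat_map` with type `"F"`, `df = c(1, n - k)`, and `sign`.
#' @export
group_contrast_map <- function(z_maps, labels, covariates = NULL, mask, grid,
                               contrast = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("design error: need exactly 2 group levels")
  if (any(table(labels) < 2)) stop("sample-size error: each group needs n >= 2")
  n <- nrow(z_maps)
  stopifnot(length(labels) == n)
  g <- as.numeric(labels == levels(labels)[1])
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (any(apply(C, 2, sd) == 0))
      stop("design error: constant covariate")
  }
  X <- cbind(rep(1, n), g, C)
  if (qr(X)$rank < ncol(X))
    stop("design error: confounded design (group collinear with covariates)")
  X0 <- cbind(rep(1, n), C)
  Q1 <- qr.Q(qr(X)); Q0 <- qr.Q(qr(X0))
  m <- as.vector(mask) != 0
  Y <- z_maps[, m, drop = FALSE]
  rss1 <- colSums((Y - Q1 %*% crossprod(Q1, Y))^2)
  rss0 <- colSums((Y - Q0 %*% crossprod(Q0, Y))^2)
  df2 <- n - ncol(X)
  good <- rss1 > 1e-24
  Fm <- rep(NA_real_, ncol(Y))
  Fm[good] <- (rss0[good] - rss1[good]) / (rss1[good] / df2)
  # adjusted group-difference sign = sign of the group coefficient
  gres <- g - drop(Q0 %*% crossprod(Q0, g))
  beta_g <- drop(crossprod(gres, Y)) / sum(gres^2)
  Fv <- rep(NA_real_, ncol(z_maps)); Sv <- rep(NA_real_, ncol(z_maps))
  Fv[m] <- Fm; Sv[m] <- sign(beta_g)
  newmask <- m; newmask[m] <- good
  if (is.null(contrast))
    contrast <- paste(levels(labels)[1], "vs", levels(labels)[2])
  stat_map(Fv, "F", c(1, df2), newmask, grid, sign = Sv, contrast = contrast)
}

#' Voxelwise statistic threshold from a two-tailed p value
#'
#' @param p two-tailed probability in (0, 1).
#' @param df degrees of freedom: scalar for t (may be `Inf` for the normal
#'   limit), length-2 (numerator, denominator) for F.
#' @param type `"t"` or `"F"`.
#' @return threshold c with `P(|T| >= c) = p` (t) or `P(F >= c) = p` (F).
#' @export
stat_threshold_from_p <- function(p, df, type = c("t", "F")) {
  type <- match.arg(type)
  stopifnot(p > 0, p < 1)
  if (type == "t") {
    if (is.infinite(df)) qnorm(1 - p / 2) else qt(1 - p / 2, df)
  } else {
    stopifnot(length(df) == 2)
    qf(1 - p, df[1], df[2])
  }
}

#' Association between cluster-mean connectivity and a covariate
#'
#' Pearson correlation (df = n - 2), partial correlation via residualisation
#' against one control covariate (df = n - 3), or a pooled-variance
#' two-sample t test when the covariate is binary.
#'
#' @param values per-subject cluster-mean connectivity.
#' @param covariate per-subject covariate (numeric; 2 distinct values are
#'   treated as a binary trait).
#' @param control optional control covariate to partial out.
#' @return list with `stat` (`r` or `t`), `estimate`, `df`, `p`.
#' @export
covariate_association <- function(values, covariate, control = NULL) {
  n <- length(values)
  stopifnot(length(covariate) == n)
  if (n < 4) stop("sample-size error: need n >= 4")
  if (sd(covariate) == 0) stop("validation error: zero-variance covariate")
  if (length(unique(covariate)) == 2 && is.null(control)) {
    gs <- split(values, covariate)
    n1 <- length(gs[[1]]); n2 <- length(gs[[2]])
    sp2 <- ((n1 - 1) * var(gs[[1]]) + (n2 - 1) * var(gs[[2]])) / (n1 + n2 - 2)
    tval <- (mean(gs[[1]]) - mean(gs[[2]])) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    return(list(stat = "t", estimate = tval, df = df,
                p = 2 * pt(-abs(tval), df)))
  }
  y <- values; x <- covariate; df <- n - 2
  if (!is.null(control)) {
    Q <- qr.Q(qr(cbind(1, control)))
    y <- y - drop(Q %*% crossprod(Q, y))
    x <- x - drop(Q %*% crossprod(Q, x))
    if (sd(x) < 1e-12)
      stop("validation error: covariate collinear with control")
    df <- n - 3
  }
  r <- cor(x, y)
  tval <- r * sqrt(df / (1 - r^2))
  list(stat = "r", estimate = r, df = df, p = 2 * pt(-abs(tval), df))
}

#' Bonferroni-adjusted per-test threshold
#'
#' @param alpha_family family-wise alpha.
#' @param m number of contrasts (>= 1).
#' @return `alpha_family / m` (reports conventionally display it rounded to
#'   3 decimals, e.g. 0.05 over 3 contrasts prints as 0.017).
#' @export
bonferroni_adjust <- function(alpha_family, m) {
  if (m < 1) stop("validation error: m must be >= 1")
  alpha_family / m
}
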