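#' Assign the prognosis group from a monthly BCVA series
#'
#' Good prognosis (Group A) means the eye reaches normal acuity at least
#' once and never drops below driving-standard acuity after the first
#' resolution of the edema: the best (minimum) logMAR value of the series
#' is <= 0 and the worst (maximum) is <= 0.15.  Every other course is
#' Group B.
#'
#' @param series numeric logMAR values from the resolution visit through
#'   month 12; `NA` entries (months before resolution) are ignored.
#' @return `"A"` or `"B"`.
#' @export
assignGroup <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) == 0L) stop("empty BCVA series")
  if (!all(is.finite(series))) stop("BCVA series must be finite")
  if (min(series) <= 0 && max(series) <= 0.15) "A" else "B"
}

#' Exact Fisher test for r x c contingency tables
#'
#' Freeman-Halton extension of Fisher's exact test: the two-sided p-value
#' is the total conditional (multivariate hypergeometric) probability of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table.  Tables are enumerated exactly, so this is
#' intended for the small tables of a clinical screen (grand total a few
#' hundred, two or three rows/columns).  Probabilities are compared with a
#' relative tolerance of 1e-7, the convention of standard exact tests.
#'
#' @param counts matrix of nonnegative integer counts, at least 2 x 2.
#' @return The two-sided p-value.
#' @export
fisherExactRxC <- function(counts) {
  counts <- as.matrix(counts)
  if (any(dim(counts) < 2L)) stop("need at least a 2 x 2 table")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) == 0) stop("empty table")
  ## all-zero rows/columns carry no information and only slow enumeration
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (any(dim(counts) < 2L)) return(1)
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  nr <- nrow(counts); nc <- ncol(counts)
  const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
  logpObs <- const - sum(lfactorial(counts))
  total <- 0
  ## depth-first enumeration over the free cells, row-major; the last cell
  ## of each row and the whole last row are determined by the margins
  recurse <- function(i, j, colRem, rowRem, acc) {
    if (i == nr) {                       # last row fixed by column remainders
      total <<- total +
        if (const - (acc + sum(lfactorial(colRem))) <= logpObs + 1e-7)
          exp(const - (acc + sum(lfactorial(colRem)))) else 0
      return(invisible())
    }
    if (j == nc) {                       # last cell of row i fixed
      v <- rowRem
      if (v <= colRem[nc])
        recurse(i + 1L, 1L, colRem - c(rep(0L, nc - 1L), v),
                rs[i + 1L], acc + lfactorial(v))
      return(invisible())
    }
    upper <- min(rowRem, colRem[j])
    for (v in 0:upper) {
      cr <- colRem; cr[j] <- cr[j] - v
      recurse(i, j + 1L, cr, rowRem - v, acc + lfactorial(v))
    }
  }
  recurse(1L, 1L, cs, rs[1L], 0)
  min(total, 1)
}

#' Two-sample Kolmogorov-Smirnov test (asymptotic)
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution with effective sample
#' size `na * nb / (na + nb)` (computed by [stats::ks.test()] with
#' `exact = FALSE`).
#'
#' @param a,b numeric samples.
#' @return list with elements `statistic` (D) and `p.value`.
#' @export
ksTwoSample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the paired differences.  Zero differences are
#' dropped; if all differences are zero the p-value is 1.  For 25 or fewer
#' nonzero differences the null distribution of the signed-rank statistic
#' is computed exactly by enumerating all sign assignments (ties in the
#' absolute differences are handled by mid-ranks, which the enumeration
#' accommodates); for larger samples a tie-corrected normal approximation
#' is used.  The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y paired numeric samples of equal length.
#' @return The two-sided p-value.
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    ## DP over doubled ranks (mid-ranks are half-integers); counts[k+1] =
    ## number of sign assignments with doubled statistic k
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    tot <- 2^n
    w2 <- round(2 * w)
    pLe <- sum(counts[seq_len(w2 + 1L)]) / tot
    pGe <- sum(counts[(w2 + 1L):length(counts)]) / tot
    min(1, 2 * min(pLe, pGe))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' R-squared of one variable regressed on all the others
#'
#' Least-squares coefficient of determination of column `j` of `X` on the
#' remaining columns plus an intercept; the quantity behind the variance
#' inflation factor (VIF = 1 / (1 - R2)).  A rank-deficient design is
#' handled through the SVD minimum-norm solution, and a constant column
#' (zero variance) returns 1 so that it is treated as fully redundant.
#'
#' @param X numeric matrix (samples x variables), at least two columns.
#' @param j index of the target column.
#' @return R-squared in [0, 1].
#' @export
r2AgainstOthers <- function(X, j) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two variables")
  stopifnot(j >= 1L, j <= ncol(X))
  y <- X[, j]
  tss <- sum((y - mean(y))^2)
  if (tss <= .Machine$double.eps * length(y)) return(1)
  Z <- cbind(1, X[, -j, drop = FALSE])
  sv <- svd(Z)
  pos <- sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1]
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  rss <- sum((y - Z %*% beta)^2)
  min(max(1 - rss / tss, 0), 1)
}

#' Iterative multicollinearity elimination by the R-squared rule
#'
#' Repeatedly computes each variable's R-squared against the others and
#' removes the single variable with the highest value while that maximum
#' exceeds the threshold (strictly); ties are broken toward the earlier
#' column.  Terminates with every retained variable at or below the
#' threshold (equivalently, VIF at or below 10 for the default 0.9).
#'
#' @param X numeric matrix with named columns (samples x variables).
#' @param names optional column names overriding `colnames(X)`.
#' @param threshold elimination threshold on R-squared (default 0.9).
#' @return list with `retained` (names kept, in original order), `removed`
#'   (names eliminated, in removal order), and `r2` (named final
#'   R-squared values of the retained set; `NA` for a single survivor).
#' @export
vifEliminate <- function(X, names = colnames(X), threshold = 0.9) {
  X <- as.matrix(X)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(X)))
  colnames(X) <- names
  removed <- character(0)
  repeat {
    if (ncol(X) < 2L) {
      r2 <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
      break
    }
    r2 <- vapply(seq_len(ncol(X)), function(j) r2AgainstOthers(X, j), 0)
    names(r2) <- colnames(X)
    if (max(r2) > threshold) {
      drop <- which.max(r2)              # first index on ties
      removed <- c(removed, colnames(X)[drop])
      X <- X[, -drop, drop = FALSE]
    } else break
  }
  list(retained = colnames(X), removed = removed, r2 = r2)
}

.defaultCategorical <- c("sex", "occlusion_type", "eye", "semifield",
                         "elm_continuity_cat", "ez_continuity_cat")

#' Screen candidate explanatory variables
#'
#' Applies the two-sample Kolmogorov-Smirnov test to each continuous
#' variable and the exact Fisher r x c test to each categorical variable,
#' comparing the two prognosis groups; variables with p strictly below
#' `alpha` become candidates, and the candidate set is then pruned with
#' [vifEliminate()] (grades entering the design matrix as numeric 0/1/2).
#' No multiple-testing correction is applied.
#'
#' @param data data.frame with a group column and the candidate variables;
#'   e.g. the output of [cohortFeatures()].  Columns named `id` are
#'   ignored.  Missing values are an error.
#' @param group name of the group column (levels `"A"`/`"B"`).
#' @param categorical names of the categorical variables; defaults to the
#'   non-numeric columns plus the two continuity grades.
#' @param alpha significance level (default 0.05, strict `<`).
#' @param r2Threshold multicollinearity threshold (default 0.9).
#' @return A [CandidateScreen-class] object.
#' @export
selectCandidates <- function(data, group = "group", categorical = NULL,
                             alpha = 0.05, r2Threshold = 0.9) {
  stopifnot(group %in% names(data))
  vars <- setdiff(names(data), c(group, "id"))
  if (anyNA(data[vars])) stop("missing values in the explanatory variables")
  g <- as.character(data[[group]])
  if (length(unique(g)) != 2L) stop("exactly two groups required")
  if (is.null(categorical))
    categorical <- union(vars[!vapply(data[vars], is.numeric, TRUE)],
                         intersect(.defaultCategorical, vars))
  rows <- lapply(vars, function(v) {
    if (v %in% categorical) {
      tab <- table(g, data[[v]])
      p <- if (ncol(tab) < 2L) 1 else fisherExactRxC(unclass(tab))
      data.frame(variable = v, type = "categorical", test = "fisher_exact", p = p)
    } else {
      p <- ksTwoSample(data[[v]][g == g[1]], data[[v]][g != g[1]])$p.value
      data.frame(variable = v, type = "continuous", test = "ks_two_sample", p = p)
    }
  })
  screen <- do.call(rbind, rows)
  screen$selected <- screen$p < alpha
  cand <- screen$variable[screen$selected]
  if (length(cand) >= 2L) {
    Xc <- as.matrix(data.frame(lapply(data[cand], asNumericCovariate)))
    colnames(Xc) <- cand
    vif <- vifEliminate(Xc, threshold = r2Threshold)
    retained <- vif$retained
    r2 <- vif$r2
  } else {
    retained <- as.character(cand)
    r2 <- stats::setNames(rep(NA_real_, length(cand)), cand)
  }
  new("CandidateScreen", screen = screen, retained = retained, r2 = r2,
      alpha = alpha, r2Threshold = r2Threshold)
}
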