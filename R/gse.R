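# Gene-set enrichment over an assignment profile.  The count-based methods
# model per-gene peak counts with a negative-binomial regression
#   log mu_g = b0 + b1 * member_g + f(log10 locus_length_g)
# where f absorbs the locus-length confounder (longer loci catch more peaks
# regardless of biology).  The dispersion theta is estimated once on the
# null (no-membership) model and reused across terms, so the approximate
# score test needs only one model fit per peak set.

#' Specify a gene-set-enrichment model
#'
#' @param method `nb_score` (approximate score test of the membership
#'   coefficient from the null fit), `nb_lrt` (likelihood-ratio chi-square
#'   with one degree of freedom at fixed dispersion), `fisher` (two-sided
#'   Fisher's exact test on has-peak by membership), or `binomial`
#'   (one-sided locus-length-proportional peak-count test).
#' @param length_adjustment `spline_log_length` (natural cubic spline on
#'   log10 locus length, the default), `linear_log_length`, or `none`.
#' @param spline_df spline degrees of freedom (>= 3).
#' @param use_weights use the profile's `weighted_count` (per-peak weights
#'   accumulated at assignment time, rounded to integers) instead of raw
#'   counts for the NB methods.
#' @return object of class `GSEModelSpec`.
#' @export
gse_model_spec <- function(method = c("nb_score", "nb_lrt", "fisher",
                                      "binomial"),
                           length_adjustment = c("spline_log_length",
                                                 "linear_log_length", "none"),
                           spline_df = 5L, use_weights = FALSE) {
  method <- match.arg(method)
  length_adjustment <- match.arg(length_adjustment)
  if (length_adjustment == "spline_log_length" && spline_df < 3L) {
    stop("spline_df must be >= 3")
  }
  structure(list(method = method, length_adjustment = length_adjustment,
                 spline_df = as.integer(spline_df),
                 use_weights = isTRUE(use_weights)),
            class = "GSEModelSpec")
}

.length_design <- function(loglen, spec) {
  n_unique <- length(unique(loglen))
  adj <- spec$length_adjustment
  if (adj == "spline_log_length" && n_unique <= spec$spline_df) {
    adj <- "linear_log_length"  # not enough distinct lengths for the basis
  }
  if (adj == "linear_log_length" && n_unique < 2L) adj <- "none"
  switch(adj,
    none = NULL,
    linear_log_length = matrix(loglen, ncol = 1L,
                               dimnames = list(NULL, "loglen")),
    spline_log_length = {
      b <- splines::ns(loglen, df = spec$spline_df)
      colnames(b) <- paste0("ns", seq_len(ncol(b)))
      unclass(b)
    })
}

# null NB fit; returns list(fit, theta, poisson_fallback)
.fit_null_nb <- function(y, X) {
  df <- if (is.null(X)) data.frame(y = y) else data.frame(y = y, X)
  fml <- if (is.null(X)) y ~ 1 else y ~ .
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = df,
                                  control = stats::glm.control(maxit = 50))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && is.finite(fit$theta) &&
      fit$theta > 0) {
    return(list(fit = fit, theta = fit$theta, poisson = FALSE))
  }
  warning("NB dispersion estimation failed; falling back to Poisson")
  fit <- stats::glm(fml, data = df, family = stats::poisson())
  list(fit = fit, theta = Inf, poisson = TRUE)
}

# one-degree score test for adding column x to a fitted null glm
.glm_score_test <- function(fit0, x) {
  w <- fit0$weights        # IRLS working weights at convergence
  r <- fit0$residuals      # working residuals (y - mu) * deta/dmu
  U <- sum(w * r * x)
  ux <- qr.resid(fit0$qr, sqrt(w) * x)
  V <- sum(ux^2)
  if (V <= .Machine$double.eps * sum(w * x^2)) return(NULL)  # collinear
  z <- U / sqrt(V)
  list(statistic = z, p = 2 * stats::pnorm(-abs(z)), sign = sign(z))
}

.clamp_p <- function(p) pmin(1, pmax(p, .Machine$double.xmin))

#' Gene-set enrichment test
#'
#' Runs the method in `spec` for every term of `sets` whose gene set,
#' intersected with the profile's gene universe, has between `min_size` and
#' `max_size` members.  Terms with zero or all universe genes are skipped
#' (recorded in the `skipped` attribute).  FDR is Benjamini-Hochberg over
#' all tested terms.
#'
#' @param profile `AssignmentProfile` from [assign_peaks()].
#' @param sets `GeneSetCollection`.
#' @param spec `GSEModelSpec`.
#' @param min_size,max_size term-size bounds after universe intersection.
#' @return `GSEResult`: data frame `term_id, n_set_genes, statistic,
#'   direction, p_value, fdr`.
#' @export
gse_test <- function(profile, sets, spec = gse_model_spec(),
                     min_size = 15L, max_size = 2000L) {
  g <- profile$genes[profile$genes$locus_length > 0, , drop = FALSE]
  universe <- g$gene_id
  y <- if (spec$use_weights) as.integer(round(g$weighted_count)) else
    g$peak_count
  term_genes <- lapply(sets$terms, intersect, y = universe)
  sizes <- lengths(term_genes)
  skipped <- names(sets$terms)[sizes == 0L | sizes == length(universe) |
                                 sizes < min_size | sizes > max_size]
  test_ids <- setdiff(names(sets$terms), skipped)
  if (length(test_ids) == 0L) {
    res <- data.frame(term_id = character(), n_set_genes = integer(),
                      statistic = numeric(), direction = character(),
                      p_value = numeric(), fdr = numeric())
    class(res) <- c("GSEResult", "data.frame")
    attr(res, "skipped") <- skipped
    return(res)
  }

  null_env <- NULL
  if (spec$method %in% c("nb_score", "nb_lrt")) {
    X <- .length_design(log10(g$locus_length), spec)
    null_env <- .fit_null_nb(y, X)
    null_env$X <- X
  }

  rows <- lapply(test_ids, function(id) {
    mem <- as.numeric(universe %in% term_genes[[id]])
    out <- switch(spec$method,
      nb_score = {
        st <- .glm_score_test(null_env$fit, mem)
        if (is.null(st)) return(NULL)
        c(stat = st$statistic, p = st$p, enr = st$sign >= 0)
      },
      nb_lrt = {
        fam <- if (is.finite(null_env$theta)) {
          MASS::negative.binomial(null_env$theta)
        } else stats::poisson()
        df_full <- if (is.null(null_env$X)) data.frame(y = y, mem = mem) else
          data.frame(y = y, null_env$X, mem = mem)
        full <- tryCatch(
          suppressWarnings(stats::glm(y ~ ., data = df_full, family = fam)),
          error = function(e) NULL)
        if (is.null(full) || is.na(stats::coef(full)["mem"])) return(NULL)
        lrt <- max(0, null_env$fit$deviance - full$deviance)
        c(stat = lrt, p = stats::pchisq(lrt, df = 1L, lower.tail = FALSE),
          enr = unname(stats::coef(full)["mem"]) >= 0)
      },
      fisher = {
        a <- sum(mem == 1 & g$has_peak); b <- sum(mem == 1 & !g$has_peak)
        cc <- sum(mem == 0 & g$has_peak); d <- sum(mem == 0 & !g$has_peak)
        ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L,
                                        byrow = TRUE))
        c(stat = unname(ft$estimate), p = ft$p.value,
          enr = unname(ft$estimate) >= 1)
      },
      binomial = {
        n <- profile$n_assigned_peaks
        if (n == 0L) return(NULL)
        in_set <- profile$peak_gene$gene_id %in% term_genes[[id]]
        k <- length(unique(profile$peak_gene$peak[in_set]))
        p0 <- sum(g$locus_length[mem == 1]) / sum(g$locus_length)
        c(stat = k,
          p = stats::pbinom(k - 1L, n, p0, lower.tail = FALSE),
          enr = k / n >= p0)
      })
    out
  })
  names(rows) <- test_ids
  ok <- !vapply(rows, is.null, logical(1L))
  skipped <- c(skipped, test_ids[!ok])
  rows <- rows[ok]
  res <- data.frame(
    term_id = names(rows),
    n_set_genes = sizes[names(rows)],
    statistic = vapply(rows, `[[`, 0, "stat"),
    direction = ifelse(vapply(rows, `[[`, 0, "enr") > 0,
                       "enriched", "depleted"),
    p_value = .clamp_p(vapply(rows, `[[`, 0, "p")),
    row.names = NULL, stringsAsFactors = FALSE)
  res$fdr <- bh_fdr(res$p_value)
  class(res) <- c("GSEResult", "data.frame")
  attr(res, "skipped") <- skipped
  attr(res, "theta") <- if (!is.null(null_env)) null_env$theta else NA_real_
  res
}
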