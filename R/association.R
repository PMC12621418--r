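#' Standardize an environmental table
#'
#' Centers each physicochemical variable to mean 0 and scales it to unit
#' standard deviation, so that regression coefficients and the key-metabolite
#' threshold are comparable across variables measured in different units
#' (pH, dS/m, %, mg/kg).
#'
#' @param env Data frame or matrix, one row per site (rownames = site ids),
#'   one numeric column per variable; missing values are an error.
#' @return Standardized data.frame with the same dimnames.
#' @export
standardize_env <- function(env) {
  env <- as.data.frame(env)
  if (anyNA(env)) stop2("environmental table contains missing values")
  if (is.null(rownames(env))) stop2("environmental table must have site rownames")
  for (v in names(env)) {
    x <- env[[v]]
    if (!is.numeric(x)) stop2("variable '", v, "' is not numeric")
    if (length(unique(x)) < 2L || stats::sd(x) == 0)
      stop2("variable '", v, "' is constant and cannot be standardized")
    env[[v]] <- as.numeric(scale(x))
  }
  env
}

#' Build the regression design from metabolite groups and environment
#'
#' Predictors are the metabolite groups' binary producibility values;
#' responses are the sites' standardized measurements. Two observation
#' designs are available:
#' \describe{
#'   \item{`"simulation"` (default)}{one observation per simulation column
#'     (site x scale x condition); the site's measurement is replicated
#'     across its simulations. Cross-validation must then be grouped by
#'     site (see [fit_elastic_net()]).}
#'   \item{`"site"`}{one observation per site; predictor values are the
#'     group's mean producibility over the site's simulations.}
#' }
#'
#' @param groups An `msc_groups` object.
#' @param env Standardized environmental table (see [standardize_env()]).
#' @param design `"simulation"` or `"site"`.
#' @return List with `X` (observations x groups numeric matrix), `Y`
#'   (observations x variables response matrix), `site` (per-observation
#'   site), and `zero_variance` (ids of constant predictor columns).
#' @export
build_design <- function(groups, env, design = c("simulation", "site")) {
  design <- match.arg(design)
  columns <- attr(groups, "columns")
  gm <- group_matrix(groups)           # groups x simulations
  if (design == "simulation") {
    X <- t(gm)
    site <- columns$site[match(rownames(X), columns$sim_id)]
  } else {
    sites <- sort_ids(columns$site)
    X <- do.call(rbind, lapply(sites, function(s)
      rowMeans(gm[, columns$sim_id[columns$site == s], drop = FALSE])))
    rownames(X) <- sites
    site <- sites
  }
  unmapped <- setdiff(unique(site), rownames(env))
  if (length(unmapped))
    stop2("site(s) not present in the environmental table: ",
          paste(unmapped, collapse = ", "))
  Y <- as.matrix(env[site, , drop = FALSE])
  rownames(Y) <- rownames(X)
  zero_var <- colnames(X)[apply(X, 2L, function(x) length(unique(x)) == 1L)]
  list(X = X, Y = Y, site = site, design = design, zero_variance = zero_var)
}

#' Fit an elastic net for one environmental variable
#'
#' Penalized least squares with mixing parameter `alpha` between lasso
#' (`alpha = 1`) and ridge (`alpha = 0`); the default 0.85 is
#' predominantly sparse. The penalty strength is chosen by cross-validation
#' grouped by site (every observation of a site is in the same fold), which
#' avoids leakage from site-level response replication; with fewer
#' observations than sites this degenerates to leave-one-site-out (a
#' warning is emitted). Among the cross-validated penalties the
#' one-standard-error rule is used by default: the site-grouped error curve
#' has very few effective replicates, and the error-minimizing penalty is
#' then noisy enough to admit frequent spurious selections (`penalty =
#' "min"` restores the error-minimizing choice).
#'
#' The response is standardized before fitting; predictors are binary
#' producibility states and are deliberately not rescaled, so a
#' coefficient reads "response change, in standard deviations, when the
#' group becomes producible" and the fixed selection threshold is
#' comparable across variables and across groups.
#'
#' @param X Observations x predictors matrix (binary producibility values).
#' @param y Numeric response vector.
#' @param site Per-observation site ids defining the CV folds.
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param penalty `"1se"` (default) or `"min"`, the cross-validation rule.
#' @param lambda Optional fixed penalty; skips cross-validation.
#' @param seed Integer seed recorded with the fit (CV folds are fully
#'   determined by `site`, so this is provenance more than randomness).
#' @return An object of class `msc_assoc`: `coefficients` (named; response
#'   at unit variance, binary predictor scale), `coefficients_scaled`
#'   (additionally multiplied by the predictor standard deviation),
#'   `intercept`, `lambda`, `alpha`, `nobs`, `seed`.
#' @export
fit_elastic_net <- function(X, y, site, alpha = 0.85,
                            penalty = c("1se", "min"), lambda = NULL,
                            seed = 1L) {
  stopifnot(nrow(X) == length(y), length(site) == length(y))
  penalty <- match.arg(penalty)
  if (stats::sd(y) == 0) stop2("response is constant; nothing to fit")
  y_std <- as.numeric(scale(y))
  foldid <- as.integer(factor(site))
  if (nrow(X) < length(unique(foldid)))
    warn2("fewer observations than sites; cross-validation degenerates to leave-one-out")
  set.seed(seed)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(X, y_std, alpha = alpha, foldid = foldid,
                            standardize = FALSE)
    lambda <- if (penalty == "1se") cv$lambda.1se else cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(X, y_std, alpha = alpha, lambda = lambda,
                          standardize = FALSE)
  }
  cf <- as.numeric(stats::coef(fit, s = lambda))
  names(cf) <- c("(Intercept)", colnames(X))
  beta <- cf[-1L]
  sds <- apply(X, 2L, stats::sd)
  structure(list(coefficients = beta, coefficients_scaled = beta * sds,
                 intercept = unname(cf[1L]), lambda = lambda, alpha = alpha,
                 penalty = penalty, nobs = nrow(X), seed = seed),
            class = "msc_assoc")
}

#' @export
print.msc_assoc <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<elastic-net fit: %d/%d nonzero coefficients, lambda = %.4g, alpha = %.2f>\n",
              nz, length(x$coefficients), x$lambda, x$alpha))
  invisible(x)
}

#' Fit elastic nets for every environmental variable
#'
#' @param design Output of [build_design()].
#' @param alpha Elastic-net mixing parameter.
#' @param penalty Cross-validation penalty rule (see [fit_elastic_net()]).
#' @param seed Integer seed.
#' @return List of `msc_assoc` fits, one per variable; the `coef_matrix`
#'   attribute is the groups x variables coefficient matrix.
#' @export
associate_all <- function(design, alpha = 0.85, penalty = "1se", seed = 1L) {
  vars <- colnames(design$Y)
  fits <- lapply(vars, function(v)
    fit_elastic_net(design$X, design$Y[, v], design$site, alpha = alpha,
                    penalty = penalty, seed = seed))
  names(fits) <- vars
  cm <- vapply(fits, `[[`, numeric(ncol(design$X)), "coefficients")
  rownames(cm) <- colnames(design$X)
  attr(fits, "coef_matrix") <- cm
  fits
}

#' Select key metabolites from elastic-net fits
#'
#' A metabolite group is selected when the absolute value of its
#' standardized coefficient exceeds `threshold` (strictly) for at least one
#' environmental variable; the key metabolites are the union of the
#' selected groups' members. Selection is monotone in the threshold.
#'
#' @param fits Output of [associate_all()] (or a named list of `msc_assoc`).
#' @param groups The `msc_groups` object the design was built from.
#' @param threshold Absolute-coefficient cutoff (default 0.3, strict).
#' @return An object of class `msc_keyset`: `selected_groups`,
#'   `key_metabolites`, `coef_table` (long data.frame of the selected
#'   groups' signed coefficients per variable), `coef_matrix` (selected
#'   groups x variables, heatmap-ready), `threshold`.
#' @export
select_key_metabolites <- function(fits, groups, threshold = 0.3) {
  cm <- attr(fits, "coef_matrix")
  if (is.null(cm)) {
    cm <- vapply(fits, `[[`, numeric(length(fits[[1]]$coefficients)),
                 "coefficients")
    rownames(cm) <- names(fits[[1]]$coefficients)
  }
  sel <- rownames(cm)[apply(abs(cm) > threshold, 1L, any)]
  key <- sort_ids(unlist(lapply(groups[sel], `[[`, "members"), use.names = FALSE))
  long <- which(abs(cm) > threshold, arr.ind = TRUE)
  coef_table <- data.frame(
    group = rownames(cm)[long[, 1L]],
    variable = colnames(cm)[long[, 2L]],
    coefficient = cm[long],
    size = vapply(rownames(cm)[long[, 1L]], function(g)
      length(groups[[g]]$members), integer(1)),
    row.names = NULL
  )
  coef_table <- coef_table[order(coef_table$group, coef_table$variable,
                                 method = "radix"), , drop = FALSE]
  rownames(coef_table) <- NULL
  structure(list(selected_groups = sort_ids(sel),
                 key_metabolites = key,
                 coef_table = coef_table,
                 coef_matrix = cm[sort_ids(sel), , drop = FALSE],
                 threshold = threshold),
            class = "msc_keyset")
}

#' @export
print.msc_keyset <- function(x, ...) {
  cat(sprintf("<key-metabolite set: %d groups, %d metabolites (|coef| > %g)>\n",
              length(x$selected_groups), length(x$key_metabolites), x$threshold))
  invisible(x)
}

#' Cluster environmental variables by coefficient profiles
#'
#' Agglomerative clustering (Ward's method, `ward.D2`) of environmental
#' variables on Bray-Curtis dissimilarities between their absolute
#' coefficient profiles across the selected metabolite groups, mirroring
#' the heatmap column clustering that delineates groups of environmental
#' variables.
#'
#' @param coef_matrix Selected groups x variables coefficient matrix (e.g.
#'   `keyset$coef_matrix`).
#' @param k Number of flat clusters to cut (default 3).
#' @return List with `hclust` (the dendrogram) and `clusters` (named
#'   cluster membership per variable).
#' @export
cluster_variables <- function(coef_matrix, k = 3L) {
  if (ncol(coef_matrix) < 2L) stop2("need at least two variables to cluster")
  prof <- t(abs(coef_matrix))          # variables x groups
  zero <- rownames(prof)[rowSums(prof) == 0]
  if (length(zero))
    stop2("variable(s) with all-zero coefficient profiles: ",
          paste(zero, collapse = ", "))
  d <- vegan::vegdist(prof, method = "bray")
  hc <- stats::hclust(d, method = "ward.D2")
  k <- min(k, ncol(coef_matrix))
  list(hclust = hc, clusters = stats::cutree(hc, k = k))
}

#' Write the selected-coefficient table as TSV
#' @param keyset An `msc_keyset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_keyset_tsv <- function(keyset, path) {
  utils::write.table(keyset$coef_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
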