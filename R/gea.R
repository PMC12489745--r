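#' Prune environmental predictors by correlation and VIF
#'
#' Two stages. First, pairwise Pearson correlation: walking the variables in
#' their given order, a variable is dropped when it correlates above `r_max`
#' in absolute value with an already-kept (earlier-listed) variable; the
#' alternative member of each pair is logged. Second, variance inflation:
#' among the kept variables the one with the largest VIF is removed and the
#' VIFs recomputed, until all are at or below `vif_max`. The VIF-stage
#' removals are returned separately — they form the conditioning set for the
#' partial ordination downstream.
#'
#' @param env tibble with an `id` column and numeric environmental variables;
#'   no missing values.
#' @param r_max pairwise correlation cutoff (default 0.7).
#' @param vif_max VIF cutoff (default 3).
#' @return object of class `env_prep`: `kept` (tibble id + variables),
#'   `conditioned` (tibble id + VIF-removed variables), `log` tibble.
#' @export
prep_env <- function(env, r_max = 0.7, vif_max = 3) {
  env <- as_tibble(env)
  vars <- setdiff(names(env), "id")
  if (length(vars) < 2) stop("need at least 2 environmental variables")
  if (anyNA(env[vars])) stop("environmental table contains missing values")
  X <- as.matrix(env[vars])
  log <- list()
  # stage 1: correlation pruning, keep the first-listed of each pair
  kept <- character(0)
  for (v in vars) {
    partner <- NULL
    for (u in kept) {
      if (abs(cor(X[, u], X[, v])) > r_max) { partner <- u; break }
    }
    if (is.null(partner)) {
      kept <- c(kept, v)
    } else {
      log[[length(log) + 1]] <- tibble(
        stage = "correlation", variable = v,
        detail = sprintf("|r| = %.3f with kept '%s'", cor(X[, partner], X[, v]),
                         partner),
        action = "dropped")
    }
  }
  # stage 2: sequential VIF removal
  conditioned <- character(0)
  repeat {
    if (length(kept) < 2) break
    vifs <- vapply(kept, function(v) {
      r2 <- summary(lm(X[, v] ~ X[, setdiff(kept, v), drop = FALSE]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
    if (max(vifs) <= vif_max) break
    worst <- kept[which.max(vifs)]
    log[[length(log) + 1]] <- tibble(
      stage = "vif", variable = worst,
      detail = sprintf("VIF = %.2f", max(vifs)), action = "to conditioning set")
    conditioned <- c(conditioned, worst)
    kept <- setdiff(kept, worst)
  }
  if (length(kept) < 1) stop("no environmental variable survived pruning")
  structure(list(
    kept = env[c("id", kept)],
    conditioned = env[c("id", conditioned)],
    log = if (length(log)) dplyr::bind_rows(log) else
      tibble(stage = character(), variable = character(),
             detail = character(), action = character())
  ), class = "env_prep")
}

#' @export
print.env_prep <- function(x, ...) {
  cat(sprintf("<env_prep> kept %d variable(s); %d moved to conditioning set\n",
              ncol(x$kept) - 1, ncol(x$conditioned) - 1))
  invisible(x)
}

#' Individual allele frequencies from dosages
#'
#' The per-individual frequency of the alternate allele is `dosage / 2`;
#' missing genotypes are imputed with the site mean frequency. This is the
#' response matrix of the ordination and latent-factor models.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric matrix, individuals x sites, entries in \[0, 1\].
#' @export
individual_allele_freq <- function(gm) {
  Y <- gm$dosages / 2
  mu <- colMeans(Y, na.rm = TRUE)
  na_idx <- which(is.na(Y))
  if (length(na_idx)) Y[na_idx] <- mu[((na_idx - 1) %/% nrow(Y)) + 1]
  Y
}

#' SD-loading candidate SNPs from a partial RDA
#'
#' On each retained axis, flags SNPs whose loading lies more than
#' `sd_mult` standard deviations from the mean loading; the union over axes
#' is the candidate set. Each candidate is assigned the environmental
#' variable with the largest absolute Pearson correlation to its individual
#' allele frequencies.
#'
#' @param res a [prda()] fit.
#' @param retained_axes number of leading constrained axes to use (default 3).
#' @param sd_mult SD cutoff, e.g. 2.5 or 3.
#' @param X optional environmental table (tibble with `id` or plain matrix);
#'   defaults to the predictors stored in the fit.
#' @return tibble of class `candidate_set`: `site`, `axis` (first axis that
#'   flagged the SNP), `variable`, `cor` with attributes `sd_mult` and
#'   `evidence = "rda"`.
#' @export
rda_candidates <- function(res, retained_axes = 3, sd_mult = 3, X = NULL) {
  stopifnot(inherits(res, "prda_fit"))
  if (sd_mult <= 0) stop("sd_mult must be positive")
  V <- res$loadings
  retained_axes <- min(retained_axes, ncol(V))
  if (is.null(X)) X <- res$X
  Xm <- .env_matrix(X)
  flagged <- integer(0)
  first_axis <- integer(0)
  for (ax in seq_len(retained_axes)) {
    l <- V[, ax]
    hit <- which(abs(l - mean(l)) > sd_mult * sd(l))
    new <- setdiff(hit, flagged)
    flagged <- c(flagged, new)
    first_axis <- c(first_axis, rep(ax, length(new)))
  }
  if (length(flagged) == 0) {
    out <- tibble(site = character(), axis = integer(),
                  variable = character(), cor = numeric())
  } else {
    cc <- abs(cor(res$Y[, flagged, drop = FALSE], Xm))
    best <- max.col(cc, ties.method = "first")
    out <- tibble(
      site = rownames(V)[flagged], axis = first_axis,
      variable = colnames(Xm)[best],
      cor = cc[cbind(seq_along(flagged), best)]
    )
  }
  attr(out, "sd_mult") <- sd_mult
  attr(out, "evidence") <- "rda"
  class(out) <- c("candidate_set", class(out))
  out
}

.env_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "id")])
  X
}

#' Intersect the three evidence sets into final candidates
#'
#' The final candidate set keeps only SNPs flagged by all three methods:
#' the SD-loading candidates of the partial RDA, the latent-factor
#' associations significant at their FDR, and the PCA-Mahalanobis outlier
#' scan. Candidates keep the RDA-assigned environmental variable; a
#' per-variable count summary is attached.
#'
#' @param rda a `candidate_set` from [rda_candidates()].
#' @param lfmm an [lfmm_scan()] fit (its significant SNPs are used) or a
#'   character vector of site ids.
#' @param scan_outliers an [outlier_scan()] fit or character vector of site
#'   ids.
#' @param universe optional character vector of all site ids, used to verify
#'   the three inputs live on a common site universe.
#' @return tibble of class `candidate_set` with evidence flag columns and a
#'   `summary` attribute (per-variable counts).
#' @export
intersect_candidates <- function(rda, lfmm, scan_outliers, universe = NULL) {
  lf_sites <- if (is.character(lfmm)) lfmm else significant_sites(lfmm)
  sc_sites <- if (is.character(scan_outliers)) scan_outliers else
    outlier_sites(scan_outliers)
  sets <- list(rda = rda$site, lfmm = lf_sites, scan = sc_sites)
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      if (length(sets[[nm]]) && !all(sets[[nm]] %in% universe)) {
        stop("candidate sites outside the shared site universe (", nm, ")")
      }
    }
  }
  final_sites <- Reduce(intersect, sets)
  out <- rda[rda$site %in% final_sites, , drop = FALSE]
  out$rda <- TRUE
  out$lfmm <- TRUE
  out$scan <- TRUE
  summary <- out |> dplyr::count(.data$variable, name = "n_snps")
  attr(out, "summary") <- summary
  attr(out, "evidence") <- "rda+lfmm+scan"
  class(out) <- unique(c("candidate_set", class(out)))
  out
}

#' Write a candidate summary shaped as method x threshold x variable counts
#'
#' @param x a `candidate_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_candidate_summary <- function(x, path) {
  s <- attr(x, "summary")
  obj <- list(evidence = attr(x, "evidence"),
              sd_mult = attr(x, "sd_mult"),
              n_candidates = nrow(x),
              per_variable = if (!is.null(s)) {
                setNames(as.list(s$n_snps), s$variable)
              } else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
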