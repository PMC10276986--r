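# Power and FDR estimation over replicated simulations, with cluster-based
# counting for correlated markers.

#' Confusion counts for one rejection set
#'
#' Cross-tabulates rejections against causal labels.  At marker granularity
#' each marker is one unit.  At cluster granularity (pass `clusters`, an
#' integer membership vector partitioning the markers) a cluster is causal
#' if it contains at least one causal marker and rejected if at least one
#' member is rejected; counts are over clusters.  The false discovery
#' proportion uses the `FP / max(R, 1)` convention, so an empty rejection
#' set has FDP 0.
#'
#' @param rejected,is_causal Logical vectors of equal length.
#' @param clusters Optional integer/factor membership vector of the same
#'   length.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `r` (rejections),
#'   `n_units`, `fdp`, `granularity`.
#' @export
confusion_counts <- function(rejected, is_causal, clusters = NULL) {
  if (length(rejected) != length(is_causal)) {
    abort("`rejected` and `is_causal` must have the same length.")
  }
  if (!is.null(clusters)) {
    if (length(clusters) != length(rejected)) {
      abort("`clusters` must have the same length as `rejected`.")
    }
    cl <- as.integer(factor(clusters))
    rejected <- as.logical(tapply(rejected, cl, any))
    is_causal <- as.logical(tapply(is_causal, cl, any))
  }
  tp <- sum(rejected & is_causal)
  fp <- sum(rejected & !is_causal)
  fn <- sum(!rejected & is_causal)
  tn <- sum(!rejected & !is_causal)
  r <- tp + fp
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, r = r,
    n_units = length(rejected),
    fdp = fp / max(r, 1L),
    granularity = if (is.null(clusters)) "marker" else "cluster"
  )
}

#' Cluster markers by empirical correlation
#'
#' Units of interest for correlated data: connected components of the graph
#' joining marker pairs whose empirical Pearson correlation (on the 0/1/2
#' codes) satisfies `|r| >= threshold`.  When `blocks` (the simulator's
#' block membership) is supplied, correlations are only computed within
#' blocks — markers in different blocks are independent by construction —
#' which keeps the cost linear in the number of markers.  Without `blocks`
#' the full pairwise correlation matrix is scanned (user data; quadratic
#' in m).
#'
#' @param G Genotype matrix (individuals x markers).
#' @param threshold Correlation threshold in (0, 1\] (reference: 0.8).
#' @param blocks Optional integer block-membership vector of length
#'   `ncol(G)`.
#' @return Integer cluster membership vector of length `ncol(G)`; every
#'   marker belongs to exactly one cluster.
#' @export
cluster_markers <- function(G, threshold = 0.8, blocks = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  m <- ncol(G)
  edges <- list()
  collect_edges <- function(idx) {
    if (length(idx) < 2L) return(NULL)
    cc <- suppressWarnings(cor(G[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0                      # constant columns join nothing
    hit <- which(abs(cc) >= threshold & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    cbind(idx[hit[, 1]], idx[hit[, 2]])
  }
  if (is.null(blocks)) {
    edges <- list(collect_edges(seq_len(m)))
  } else {
    stopifnot(length(blocks) == m)
    edges <- lapply(split(seq_len(m), blocks), collect_edges)
  }
  edge_mat <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edge_mat) && nrow(edge_mat) > 0) {
    g <- igraph::add_edges(g, t(edge_mat))
  }
  as.integer(igraph::components(g)$membership)
}

# block membership implied by a design's contiguous block layout
design_blocks <- function(design) {
  rep(seq_len(ceiling(design$m / design$block_size)),
      each = design$block_size, length.out = design$m)
}

#' Summarize replicated confusion counts into power and FDR estimates
#'
#' Takes per-replicate, per-procedure counts (long tibble) and returns the
#' empirical mean and standard error (sample SD / sqrt(replicates)) of:
#' overall power `TP/m1`, per-MAF-group power `TP_g/m1_g` where subgroup
#' columns are present, and the FDR estimate `mean(FP/max(R,1))`.
#'
#' @param data Tibble with columns `procedure`, `replicate`, `tp`, `fdp`,
#'   `m1`, and optionally `tp_<group>` / `m1_<group>` pairs for the groups
#'   `rare`, `medium_rare`, `medium`, `common`.
#' @return Long tibble with columns `procedure`, `metric`, `estimate`,
#'   `se`, `replicates`.  Powers with `m1 = 0` are reported as missing.
#' @export
power_estimates <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("procedure", "tp", "fdp", "m1") %in% names(data)))
  groups <- c("rare", "medium_rare", "medium", "common")
  have <- groups[paste0("tp_", groups) %in% names(data) &
                 paste0("m1_", groups) %in% names(data)]
  one_metric <- function(d, values, metric) {
    n_rep <- length(values)
    if (n_rep == 1L) {
      warn("Single replicate: standard errors are reported as 0.")
    }
    tibble::tibble(
      metric = metric,
      estimate = mean(values),
      se = if (n_rep > 1L) sd(values) / sqrt(n_rep) else 0,
      replicates = n_rep
    )
  }
  dplyr::group_by(data, .data$procedure) |>
    dplyr::group_modify(function(d, key) {
      out <- list(
        one_metric(d, if (all(d$m1 > 0)) d$tp / d$m1 else rep(NA_real_, nrow(d)),
                   "power_overall"),
        one_metric(d, d$fdp, "fdr")
      )
      for (g in have) {
        m1g <- d[[paste0("m1_", g)]]
        vals <- if (all(m1g > 0)) d[[paste0("tp_", g)]] / m1g else rep(NA_real_, nrow(d))
        out <- c(out, list(one_metric(d, vals, paste0("power_", g))))
      }
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
}

procedure_rejections <- function(procedure, scan, x, alpha, wbha_args, seed) {
  switch(procedure,
    bh = bh_stepup(scan$p, alpha)$rejected,
    qvalue = qvalue_procedure(scan$p, alpha)$rejected,
    wbh = weighted_bh(scan$p, covariate_weights(x, 1), alpha)$rejected,
    wbha = {
      args <- c(list(p = scan$p, x = x, alpha = alpha, seed = seed), wbha_args)
      trace <- do.call(bagging_optimize, args)
      weighted_bh(scan$p, covariate_weights(x, trace$a), alpha)$rejected
    },
    abort(sprintf("Unknown procedure '%s'.", procedure))
  )
}

#' Run a replicated simulation study
#'
#' The full pipeline of the evaluation harness: for each replicate,
#' simulate a study from `design` (replicate r uses seed `seed + r`), scan
#' it with the trait-appropriate single-marker test, apply each requested
#' procedure at level `alpha`, and tabulate confusion counts — at cluster
#' granularity (correlation threshold 0.8, within simulation blocks) when
#' `design$rho > 0`, at marker granularity otherwise.  Per-MAF-group true
#' positives are always counted at marker granularity.
#'
#' The `covariate` option feeds the weighted procedures the observed MAF
#' (`"maf"`, rare-variant prioritization), its reciprocal (`"inv_maf"`,
#' common-variant prioritization), or an uninformative U(0, 1) draw
#' (`"uniform"`, robustness check).
#'
#' @param design A [simulation_design()].
#' @param procedures Subset of `c("bh", "qvalue", "wbh", "wbha")`.
#' @param replicates Number of simulated datasets (reference protocol: 500;
#'   desk-scale studies use fewer).
#' @param seed Integer root seed.
#' @param alpha Nominal FDR level (reference: 0.05).
#' @param covariate `"maf"`, `"inv_maf"`, or `"uniform"`.
#' @param wbha_args List of extra arguments for [bagging_optimize()]
#'   (e.g. `grid`, `K`).
#' @param genotypes Optional plug-in genotype matrix passed to
#'   [simulate_study()] (semi-simulation from a real panel).
#' @return A `study_summary`: the [power_estimates()] tibble with the
#'   per-replicate counts in `attr(, "replicates")` and the design, alpha
#'   and covariate choice attached as attributes.
#' @export
run_study <- function(design, procedures = c("bh", "qvalue", "wbh", "wbha"),
                      replicates = 100, seed = 1, alpha = 0.05,
                      covariate = c("maf", "inv_maf", "uniform"),
                      wbha_args = list(), genotypes = NULL) {
  stopifnot(inherits(design, "simulation_design"), replicates >= 1)
  covariate <- match.arg(covariate)
  procedures <- match.arg(procedures, several.ok = TRUE)
  groups <- c(rare = "rare", medium_rare = "medium-rare",
              medium = "medium", common = "common")
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- seed + r
    design$seed <- rep_seed
    study <- simulate_study(design, genotypes = genotypes)
    scan <- scan_study(study)
    x <- switch(covariate,
      maf = pmax(scan$covariate, 1e-4),       # guard: folded MAF can be 0
      inv_maf = 1 / pmax(scan$covariate, 1e-4),
      uniform = runif(nrow(scan))
    )
    clusters <- if (design$rho > 0) {
      cluster_markers(study$G, threshold = 0.8, blocks = design_blocks(study$design))
    } else NULL
    m1g <- table(factor(scan$maf_group[scan$is_causal], levels = groups))
    for (proc in procedures) {
      rej <- procedure_rejections(proc, scan, x, alpha, wbha_args,
                                  seed = rep_seed + 1000000L)
      cc <- confusion_counts(rej, scan$is_causal, clusters = clusters)
      row <- dplyr::mutate(cc, procedure = proc, replicate = r,
                           m1 = sum(scan$is_causal), .before = 1)
      for (g in names(groups)) {
        sel <- scan$is_causal & scan$maf_group == groups[[g]]
        row[[paste0("tp_", g)]] <- sum(rej & sel)
        row[[paste0("m1_", g)]] <- as.integer(m1g[[groups[[g]]]])
      }
      rows[[r]] <- dplyr::bind_rows(rows[[r]], row)
    }
  }
  counts <- dplyr::bind_rows(rows)
  summary <- power_estimates(counts)
  structure(summary,
            replicates = counts, design = design, alpha = alpha,
            covariate = covariate,
            class = c("study_summary", class(summary)))
}

#' @rdname run_study
#' @param x A `study_summary`.
#' @param ... Unused.
#' @export
glance.study_summary <- function(x, ...) {
  d <- attr(x, "design")
  tibble::tibble(
    n = d$n, m = d$m, m1 = d$m1, rho = d$rho, trait = d$trait,
    scenario = d$scenario, alpha = attr(x, "alpha"),
    covariate = attr(x, "covariate"),
    replicates = max(x$replicates)
  )
}

#' Plot a study summary
#'
#' Point-and-error-bar panels of the estimated power (overall and per MAF
#' subgroup) and empirical FDR by procedure, with the nominal level as a
#' dashed reference line in the FDR panel.
#'
#' @param object A `study_summary` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_summary <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    panel = ifelse(.data$metric == "fdr", "FDR", "Power"),
    metric = factor(.data$metric,
                    levels = c("power_overall", "power_rare",
                               "power_medium_rare", "power_medium",
                               "power_common", "fdr"))
  )
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$estimate,
                                   colour = .data$procedure)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$se,
                   ymax = .data$estimate + .data$se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_hline(
      data = data.frame(panel = "FDR", level = alpha),
      ggplot2::aes(yintercept = .data$level),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate", colour = "procedure") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
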