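# End-to-end orchestration: run every stage of the two-marker analysis on an
# alignment + genotype table + population map and collect the tables a
# population-genetics paper would report (diversity, pairwise
# differentiation, AMOVA, neutrality/demography, network, power).

#' Analysis run configuration
#'
#' @param model Sequence distance model (default `"K80"`).
#' @param n_perm Permutations for AMOVA/Phi_ST/F_ST tests (default 10000).
#' @param n_boot Parametric-bootstrap replicates for the mismatch fit
#'   (default 1000).
#' @param n_sim Coalescent replicates for neutrality-test significance
#'   (default 1000).
#' @param rarefaction_g Allelic-richness rarefaction size in individuals
#'   (default: smallest per-locus per-site sample).
#' @param epsilon Median-joining relaxation parameter (default 0).
#' @param min_steps Haplogroup divergence threshold in mutational steps
#'   (default 15).
#' @param clocks Named list of [clock_config()] per group (default: 3.6%/My,
#'   583 bp, generation times 2.2 y for `northern` and 5 y for `southern`).
#' @param power Power-simulation grid: list with `fst`, `ne`, `reps`,
#'   `alpha`; `NULL` disables it in [run_benguela()].
#' @param include_ld Run pairwise linkage tests (default `TRUE`).
#' @param seed Master seed for every random stage.
#' @return A `run_config` list.
#' @export
run_config <- function(model = "K80", n_perm = 10000, n_boot = 1000,
                       n_sim = 1000, rarefaction_g = NULL, epsilon = 0,
                       min_steps = 15,
                       clocks = list(northern = clock_config(3.6, 583, 2.2),
                                     southern = clock_config(3.6, 583, 5)),
                       power = list(fst = c(0.005, 0.02, 0.05),
                                    ne = c(500, 2000), reps = 1000,
                                    alpha = 0.05),
                       include_ld = TRUE, seed = 1L) {
  structure(list(model = model, n_perm = n_perm, n_boot = n_boot,
                 n_sim = n_sim, rarefaction_g = rarefaction_g,
                 epsilon = epsilon, min_steps = min_steps, clocks = clocks,
                 power = power, include_ld = include_ld,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; `clocks` is a
#' mapping `group: {rate, L, gen_time}`.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(y$clocks)) {
    args$clocks <- lapply(y$clocks, function(cl) {
      clock_config(rate = cl$rate %||% 3.6, L = cl$L %||% 583,
                   gen_time = cl$gen_time %||% 2.2)
    })
  }
  do.call(run_config, args)
}

#' Run the full two-marker population analysis
#'
#' Orchestrates every stage on the supplied data: mtDNA diversity, variable
#' and fixed sites, pairwise Phi_ST and hierarchical AMOVA, median-joining
#' network and haplogroups, neutrality tests and the sudden-expansion fit
#' with calendar-time conversion, microsatellite summaries (diversity, HWE,
#' null alleles, optional linkage), Weir-Cockerham F_ST, Jost's D, a
#' genotypic distance AMOVA, and the drift power simulation. Deterministic
#' given `config$seed`.
#'
#' @param aln Alignment tibble (or `NULL` to skip the mtDNA stages).
#' @param gt Genotype tibble (or `NULL` to skip the microsatellite stages).
#' @param popmap Population map covering all ids.
#' @param config A [run_config()].
#' @return Object of class `result_bundle`: named list of result tables and
#'   fitted objects, plus `meta` (seed, config hash, package version).
#' @export
run_benguela <- function(aln = NULL, gt = NULL, popmap, config = run_config()) {
  out <- list()
  seed <- config$seed
  groups <- unique(popmap$group)
  if (!is.null(aln)) {
    validate_popmap(aln$id, popmap)
    pm_aln <- popmap[popmap$id %in% aln$id, ]
    out$diversity <- diversity_summary(aln, popmap)
    vs <- variable_sites(aln)
    out$sites <- tibble(n_comparable = length(vs$comparable),
                        n_variable = length(vs$variable),
                        n_informative = length(vs$informative),
                        n_fixed = if (length(unique(pm_aln$group)) == 2) {
                          fixed_differences(aln, popmap)
                        } else NA_integer_)
    d <- distance_matrix(aln, config$model)
    out$amova_mtdna <- amova(d, popmap, n_perm = config$n_perm,
                             seed = derive_seed(seed, "amova_mtdna"))
    out$amova_mtdna_onelevel <- amova(d, popmap, hierarchy = "one",
                                      n_perm = config$n_perm,
                                      seed = derive_seed(seed, "amova_mt1"))
    out$phist <- pairwise_phist(d, popmap, n_perm = config$n_perm,
                                seed = derive_seed(seed, "phist"))
    site_group <- popmap |> distinct(.data$site, .data$group)
    out$phist_summary <- out$phist |>
      left_join(site_group, by = c(pop1 = "site")) |>
      rename(group1 = "group") |>
      left_join(site_group, by = c(pop2 = "site")) |>
      rename(group2 = "group") |>
      mutate(comparison = ifelse(.data$group1 == .data$group2,
                                 paste0("within ", .data$group1), "between")) |>
      group_by(.data$comparison) |>
      summarise(mean_phi_st = mean(.data$value), n_pairs = n(),
                .groups = "drop")
    ht <- collapse_haplotypes(aln, popmap)
    out$haplotypes <- ht
    net <- mj_network(ht, epsilon = config$epsilon)
    out$network <- net
    out$haplogroups <- haplogroups(net, config$min_steps)
    if (length(unique(pm_aln$group)) == 2) {
      out$min_intergroup_steps <- min_intergroup_distance(aln, popmap)
      div <- divergence_between(aln, popmap, config$model)
      rate <- config$clocks[[1]]$rate %||% 3.6
      out$net_divergence <- bind_cols(
        div,
        net_divergence_time(div$dxy, div$d_within_1, div$d_within_2, rate) |>
          select(-"dxy"))
    }
    out$neutrality <- neutrality_tests(aln, popmap, n_sim = config$n_sim,
                                       seed = derive_seed(seed, "neut"))
    pm2 <- validate_popmap(aln$id, popmap)
    fits <- list()
    times <- list()
    for (g in unique(pm2$group)) {
      sub <- aln[aln$id %in% pm2$id[pm2$group == g], ]
      attr(sub, "L") <- attr(aln, "L")
      mm <- mismatch_observed(sub)
      fit <- fit_sudden_expansion(mm, n = nrow(sub), n_boot = config$n_boot,
                                  seed = derive_seed(seed, "mismatch", g))
      fits[[g]] <- fit
      clock <- config$clocks[[g]] %||% clock_config()
      times[[g]] <- time_since_expansion(fit$tau, clock, fit$tau_ci) |>
        mutate(group = g, .before = 1)
    }
    out$expansion_fits <- fits
    out$expansion_times <- list_rbind(times)
    out$demography <- list_rbind(imap(fits, function(f, g) {
      tibble(group = g, theta0 = f$theta0, theta1 = f$theta1, tau = f$tau,
             ssd = f$ssd, p_boot = f$p_boot,
             tau_low = f$tau_ci[1], tau_high = f$tau_ci[2])
    }))
  }
  if (!is.null(gt)) {
    validate_popmap(unique(gt$id), popmap)
    out$msat_summary <- locus_summary(gt, popmap, config$rarefaction_g)
    loci <- unique(gt$locus)
    out$hwe <- list_rbind(map(loci, function(l) {
      hwe_test(gt, popmap, l, n_reps = min(config$n_perm, 1000),
               seed = derive_seed(seed, "hwe"))
    }))
    out$hwe <- out$hwe |>
      group_by(.data$site) |>
      mutate(holm_reject = sequential_bonferroni(.data$p)) |>
      ungroup()
    out$null_alleles <- null_alleles(gt, popmap)
    if (config$include_ld && length(loci) > 1) {
      pairs <- utils::combn(loci, 2)
      out$ld <- list_rbind(map(seq_len(ncol(pairs)), function(k) {
        ld_test(gt, popmap, pairs[, k], n_reps = min(config$n_perm, 1000),
                seed = derive_seed(seed, "ld"))
      }))
    }
    out$fst <- wc_fst(gt, popmap, n_perm = config$n_perm,
                      seed = derive_seed(seed, "fst"))
    out$jost_d <- jost_dest(gt, popmap)
    dmsat <- genotype_distance(gt)
    out$amova_msat <- amova(dmsat, popmap, n_perm = config$n_perm,
                            seed = derive_seed(seed, "amova_msat"))
    if (!is.null(config$power)) {
      # base frequencies from the pooled sample, as the Powsim design does
      mats <- gt_to_matrices(gt)
      base_freqs <- map(seq_along(mats$loci), function(l) {
        cnt <- tabulate(c(mats$a1[, l], mats$a2[, l])[!is.na(mats$a1[, l])],
                        mats$nalleles[l])
        cnt / sum(cnt)
      })
      sample_sizes <- popmap |> filter(.data$id %in% unique(gt$id)) |>
        count(.data$site) |> pull(.data$n)
      grid <- expand.grid(fst = config$power$fst, ne = config$power$ne)
      out$power <- list_rbind(map(seq_len(nrow(grid)), function(k) {
        glance(power_simulation(base_freqs, grid$ne[k], grid$fst[k],
                                sample_sizes, reps = config$power$reps,
                                alpha = config$power$alpha %||% 0.05,
                                seed = derive_seed(seed, "power", k)))
      }))
    }
  }
  out$meta <- tibble(
    seed = seed,
    config_hash = rlang::hash(config),
    n_perm = config$n_perm, n_boot = config$n_boot, n_sim = config$n_sim,
    package_version = as.character(utils::packageVersion("geelbek")))
  structure(out, class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle> stages: ",
      paste(setdiff(names(x), "meta"), collapse = ", "), "\n", sep = "")
  cat("seed ", x$meta$seed, ", config ", x$meta$config_hash, "\n", sep = "")
  invisible(x)
}

#' Write a result bundle to disk
#'
#' Tables go to `tables/*.tsv`, the network to `network/` (GraphML and edge
#' list), and run metadata to `meta/run.json`.
#'
#' @param bundle A `result_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  for (sub in c("tables", "network", "meta")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  wt <- function(x, name) readr::write_tsv(x, file.path(dir, "tables",
                                                        paste0(name, ".tsv")),
                                           progress = FALSE)
  tablish <- c("diversity", "sites", "phist", "phist_summary", "neutrality",
               "demography", "expansion_times", "msat_summary", "hwe",
               "null_alleles", "ld", "power")
  for (nm in intersect(tablish, names(bundle))) wt(bundle[[nm]], nm)
  if (!is.null(bundle$amova_mtdna)) {
    wt(tidy(bundle$amova_mtdna), "amova_mtdna")
    wt(bundle$amova_mtdna$phi, "amova_mtdna_phi")
  }
  if (!is.null(bundle$amova_msat)) {
    wt(tidy(bundle$amova_msat), "amova_msat")
    wt(bundle$amova_msat$phi, "amova_msat_phi")
  }
  if (!is.null(bundle$fst)) {
    wt(bundle$fst$per_locus, "fst_per_locus")
    wt(as_tibble(bundle$fst$pairwise), "fst_pairwise")
  }
  if (!is.null(bundle$jost_d)) {
    wt(bundle$jost_d$per_locus, "jost_d_per_locus")
    if (!is.null(bundle$jost_d$pairwise)) {
      wt(as_tibble(bundle$jost_d$pairwise), "jost_d_pairwise")
    }
  }
  if (!is.null(bundle$haplotypes)) {
    wt(bundle$haplotypes$haplotypes, "haplotypes")
    if (!is.null(bundle$haplotypes$counts)) wt(bundle$haplotypes$counts,
                                               "haplotype_counts")
  }
  if (!is.null(bundle$network)) {
    write_network(bundle$network, file.path(dir, "network", "network.graphml"))
    write_network(bundle$network, file.path(dir, "network", "edges.tsv"),
                  format = "edgelist")
    wt(bundle$haplogroups$membership, "haplogroups")
  }
  jsonlite::write_json(as.list(bundle$meta), file.path(dir, "meta", "run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Tile plot of a pairwise differentiation matrix
#'
#' @param x A `pairwise_stat` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 geom_tile scale_fill_viridis_c
#' @export
autoplot.pairwise_stat <- function(x, ...) {
  ggplot(x, aes(x = .data$pop1, y = .data$pop2, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = attr(x, "statistic") %||% "value") +
    labs(x = NULL, y = NULL)
}
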