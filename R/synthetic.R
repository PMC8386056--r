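#' Generate a paired source/target scenario with planted structure
#'
#' Emulates the assumptions the fusion method relies on: genes in the same
#' functional module share expression patterns, pathogenic genes have an
#' expression pattern that differs from background, and matched genes in the
#' two cohorts are correlated to a degree set by the cross-domain noise.
#'
#' Construction (latent factors, O(n d) cost): genes are split into
#' contiguous, near-equal modules; each module m has a latent profile
#' F_m over max(d_source, d_target) sample coordinates, and gene i's base
#' profile is `sqrt(rho) F_m + sqrt(1-rho) eps_i` (unit variance, so
#' within-module correlation is about `rho = within_module_corr`).
#' Pathogenic genes occupy the first module(s) and additionally get a mean
#' shift of `pathogenic_shift` (in gene SD units) on the first half of the
#' sample coordinates — a case/control-like differential pattern that
#' survives per-gene centering, unlike a constant offset. The source matrix
#' is the base profile over its d_source coordinates; the target is
#' `sqrt(1-nu) base + sqrt(nu) noise` over its d_target coordinates with
#' `nu = cross_domain_noise`, so the per-gene cross-domain correlation is
#' about `sqrt(1-nu)` and reaches 1 when nu = 0. When the two cohorts have
#' different sizes they share the first min(d_source, d_target) coordinates
#' and the remainder is independent. The planted truth network connects
#' every within-module pair with weight 1.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_modules number of co-expression modules (>= 2).
#' @param d_source,d_target samples per cohort (>= 3).
#' @param n_pathogenic planted pathogenic genes (< n_genes).
#' @param pathogenic_shift differential-expression effect size in SD units.
#' @param cross_domain_noise nu in [0, 1]: 0 = identical cohorts, 1 =
#'   unrelated.
#' @param within_module_corr rho in (0, 1): within-module correlation.
#' @param seed RNG seed; the generator is fully deterministic given it.
#' @return list(source, target, labels, truth_net, modules).
#' @export
generate_scenario <- function(n_genes, n_modules, d_source, d_target,
                              n_pathogenic, pathogenic_shift,
                              cross_domain_noise, within_module_corr, seed) {
  if (n_pathogenic >= n_genes) stop("n_pathogenic must be < n_genes", call. = FALSE)
  if (n_pathogenic < 1L) stop("need at least one pathogenic gene", call. = FALSE)
  if (n_modules < 2L) stop("need at least 2 modules", call. = FALSE)
  if (n_modules > n_genes) stop("more modules than genes", call. = FALSE)
  if (!(within_module_corr > 0 && within_module_corr < 1))
    stop("within_module_corr must be in (0,1)", call. = FALSE)
  if (cross_domain_noise < 0 || cross_domain_noise > 1)
    stop("cross_domain_noise must be in [0,1]", call. = FALSE)
  set.seed(seed)
  rho <- within_module_corr
  nu <- cross_domain_noise
  d_max <- max(d_source, d_target)

  sizes <- rep(n_genes %/% n_modules, n_modules)
  extra <- n_genes %% n_modules
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  modules <- rep(seq_len(n_modules), times = sizes)

  gid <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  fac <- matrix(stats::rnorm(n_modules * d_max), n_modules, d_max)
  base <- sqrt(rho) * fac[modules, , drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n_genes * d_max), n_genes, d_max)

  labels <- integer(n_genes)
  labels[seq_len(n_pathogenic)] <- 1L  # contiguous: concentrated in first module(s)
  names(labels) <- gid
  affected <- seq_len(floor(d_max / 2))
  base[labels == 1L, affected] <- base[labels == 1L, affected] + pathogenic_shift

  src <- base[, seq_len(d_source), drop = FALSE]
  tgt <- sqrt(1 - nu) * base[, seq_len(d_target), drop = FALSE] +
    sqrt(nu) * matrix(stats::rnorm(n_genes * d_target), n_genes, d_target)

  dimnames(src) <- list(gid, sprintf("src_s%02d", seq_len(d_source)))
  dimnames(tgt) <- list(gid, sprintf("tgt_s%02d", seq_len(d_target)))

  truth <- outer(modules, modules, "==") * 1
  dimnames(truth) <- list(gid, gid)
  diag(truth) <- 0

  list(source = expression_matrix(src),
       target = expression_matrix(tgt),
       labels = pathogenic_labels(labels),
       truth_net = weighted_network(truth),
       modules = stats::setNames(modules, gid))
}

#' Small fixed scenario used by the acceptance suite
#'
#' 120 genes in 4 modules, 40 samples per cohort, 12 pathogenic genes with
#' shift 2.0 SD, cross-domain noise 0.3, within-module correlation 0.8.
#'
#' @param seed RNG seed.
#' @return same tuple as [generate_scenario()].
#' @export
scenario_fixture_small <- function(seed) {
  generate_scenario(n_genes = 120L, n_modules = 4L, d_source = 40L,
                    d_target = 40L, n_pathogenic = 12L,
                    pathogenic_shift = 2.0, cross_domain_noise = 0.3,
                    within_module_corr = 0.8, seed = seed)
}

#' Write a scenario's four artifacts to a directory
#'
#' Emits `source.tsv`, `target.tsv`, `pathogenic.txt` and `truth_net.tsv`
#' in the package's plain-text interchange formats.
#'
#' @param scenario output of [generate_scenario()].
#' @param dir output directory (created if absent).
#' @return dir, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(scenario$source, file.path(dir, "source.tsv"))
  write_expression(scenario$target, file.path(dir, "target.tsv"))
  lab <- unclass(scenario$labels)
  writeLines(names(lab)[lab == 1L], file.path(dir, "pathogenic.txt"))
  write_network(scenario$truth_net, file.path(dir, "truth_net.tsv"))
  invisible(dir)
}
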