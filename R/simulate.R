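# Synthetic ploidy-resolved liver snRNA-seq generator. Emits a raw count
# matrix with the statistical structure the downstream analysis assumes --
# deep Smart-seq-style per-nucleus counts, ERCC spike-ins at two dilutions
# with per-nucleus capture efficiency, a calibrated 4n detection increase,
# planted strong DEGs, higher 2n dispersion, a latent lobule coordinate with
# opposite pericentral/periportal gradients, pericentral 4n enrichment, and a
# correlated binary stem-marker module -- together with full ground truth.

#' Simulation configuration
#'
#' Defaults reproduce the magnitudes of the study: a 1.25-fold 4n detection
#' increase in hepatocytes, 2n dispersion 1.5x the 4n dispersion, a 1.3-fold
#' pericentral 4n enrichment, strong planted DEGs, a six-marker stem module
#' (Axin2, Tbx3, Lgr5, Itga6, Tert, Notch2) inside the ten-marker stem panel,
#' ERCC spike-ins at two dilutions (3:1), and ~1200 nuclei x 3000 genes.
#'
#' The 4n detection increase is planted as a 4n-activated expression program:
#' `n_program` low-expressed genes are up-regulated in 4n hepatocytes by a
#' common factor calibrated (closed form, on the expected number of detected
#' genes) so that the median detected-gene fold equals `detection_fold`.
#' Program genes are genuinely differentially expressed and are part of the
#' ploidy-DE ground truth, together with the `n_deg` strong DEGs.
#'
#' The latent lobule coordinate z (0 = central vein, 1 = portal vein) is
#' uniform for 2n hepatocytes; the 4n density is `enrichment_4n_cv`-fold the
#' 2n density for all z below `enrichment_zmax`, so the planted pericentral
#' enrichment is recovered for any cluster boundary up to that point.
#'
#' @param seed random seed (mandatory).
#' @param n_hep_2n,n_hep_4n hepatocyte nuclei per ploidy.
#' @param n_other named vector of nuclei for the other cell types.
#' @param n_genes total endogenous genes.
#' @param theta_coef,theta_exp,theta_min,theta_max gene-wise NB size
#'   parameters: `theta_j = clamp(theta_coef * mu_j^theta_exp)`, at 4n scale.
#' @param dispersion_ratio_2n 2n dispersion relative to 4n (default 1.5).
#' @param detection_fold target 4n/2n median detected-gene fold (default 1.25).
#' @param n_program,program_mu_meanlog,program_mu_sdlog the 4n detection
#'   program: gene count and baseline log-normal expression.
#' @param n_deg,deg_log2fc strong DEG count (half up, half down in 4n) and
#'   absolute log2 effect.
#' @param n_pericentral,n_periportal zonated gene counts per direction
#'   (including the panel genes and the ploidy-restricted zonated genes).
#' @param n_zon_ploidy_only genes zonated only in 4n (pericentral) and only
#'   in 2n (periportal), mean-matched across ploidies.
#' @param panel_size_zonated,panel_size_nonzon sizes of the zonation panel
#'   lists reported in the ground truth (strong, highly expressed markers).
#' @param panel_mu,panel_slope,zon_only_slope,slope_range,zon_mu_meanlog,zon_mu_sdlog
#'   zonation expression parameters (slopes are exponential rates per unit z).
#' @param n_ct_markers,ct_fold,ct_off,ct_mu_meanlog,ct_mu_sdlog cell-type
#'   marker structure (fold in own type, residual fraction elsewhere).
#' @param n_housekeeping,hk_mu_meanlog,hk_mu_sdlog shared high-expressed genes.
#' @param bg_mu_meanlog,bg_mu_sdlog remaining background genes.
#' @param deg_mu_meanlog,deg_mu_sdlog,zon_only_mu_meanlog,zon_only_mu_sdlog
#'   baselines for DEGs and ploidy-restricted zonated genes.
#' @param efficiency_sdlog log-normal sd of per-nucleus capture efficiency.
#' @param enrichment_4n_cv planted pericentral 4n enrichment (default 1.3).
#' @param enrichment_zmax upper end of the constant-enrichment region.
#' @param stem_markers,stem_module stem panel and its co-expressed module.
#' @param p_stem,p_module_on,p_module_off,p_background,stem_mu stem latent
#'   state frequency, marker on-probabilities and expression level when on.
#' @param ercc_total_base expected ERCC reads per nucleus at efficiency 1 in
#'   the least-diluted group.
#' @param dilution_groups named vector of relative spike-in amounts.
#' @param n_plates,n_animals,n_tech_replicates metadata structure.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_hep_2n = 450, n_hep_4n = 550,
                       n_other = c(hepatobiliary = 100, endothelial = 100),
                       n_genes = 3000,
                       theta_coef = 0.55, theta_exp = 0.45,
                       theta_min = 0.3, theta_max = 15,
                       dispersion_ratio_2n = 1.5,
                       detection_fold = 1.25,
                       n_program = 600, program_mu_meanlog = log(0.6),
                       program_mu_sdlog = 0.4,
                       n_deg = 40, deg_log2fc = 2,
                       n_pericentral = 150, n_periportal = 150,
                       n_zon_ploidy_only = 10,
                       panel_size_zonated = 12, panel_size_nonzon = 8,
                       panel_mu = 50, panel_slope = 3,
                       slope_range = c(0.8, 2),
                       zon_mu_meanlog = log(3), zon_mu_sdlog = 0.8,
                       n_ct_markers = 30, ct_fold = 10, ct_off = 0.05,
                       ct_mu_meanlog = log(2), ct_mu_sdlog = 0.8,
                       n_housekeeping = 200, hk_mu_meanlog = log(20),
                       hk_mu_sdlog = 1,
                       bg_mu_meanlog = log(0.5), bg_mu_sdlog = 1.4,
                       deg_mu_meanlog = log(8), deg_mu_sdlog = 0.5,
                       zon_only_mu_meanlog = log(5), zon_only_mu_sdlog = 0.5,
                       zon_only_slope = 2,
                       efficiency_sdlog = 0.3,
                       enrichment_4n_cv = 1.3, enrichment_zmax = 2 / 3,
                       stem_markers = c("Icam1", "Afp", "Sox9", "Epcam",
                                        "Axin2", "Tbx3", "Itga6", "Tert",
                                        "Lgr5", "Notch2"),
                       stem_module = c("Axin2", "Tbx3", "Lgr5", "Itga6",
                                       "Tert", "Notch2"),
                       p_stem = 0.35, p_module_on = 0.8, p_module_off = 0.05,
                       p_background = 0.1, stem_mu = 8,
                       ercc_total_base = 4500,
                       dilution_groups = c("1:100000" = 1, "1:300000" = 1 / 3),
                       n_plates = 4, n_animals = 4, n_tech_replicates = 2) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (!all(cfg$stem_module %in% cfg$stem_markers)) {
    stop("stem_module must be a subset of stem_markers")
  }
  if (any(c(p_stem, p_module_on, p_module_off, p_background) < 0) ||
      any(c(p_stem, p_module_on, p_module_off, p_background) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (enrichment_4n_cv * enrichment_zmax > 1) {
    stop("enrichment_4n_cv * enrichment_zmax must not exceed 1")
  }
  if (n_pericentral < panel_size_zonated + n_zon_ploidy_only ||
      n_periportal < panel_size_zonated + n_zon_ploidy_only) {
    stop("zonated gene counts must accommodate the panel and ploidy-only genes")
  }
  n_special <- length(cfg$stem_markers) + 3 * n_ct_markers +
    2 * panel_size_zonated + panel_size_nonzon +
    (n_pericentral - panel_size_zonated) + (n_periportal - panel_size_zonated) +
    n_deg + n_program + n_housekeeping
  if (n_special + 100 > n_genes) {
    stop("infeasible config: ", n_special,
         " structured genes leave too little background for n_genes = ", n_genes)
  }
  structure(cfg, class = "sim_config")
}

#' QC thresholds matched to the synthetic depth
#'
#' The study's QC windows are calibrated to a 54k-gene, ~200k-read matrix.
#' These are the same windows rescaled to the generator's depth (3000 genes,
#' ~15k reads per nucleus): scale-free thresholds (ERCC fraction window,
#' normalized-total cap) are unchanged.
#'
#' @return a [qc_thresholds()] object.
#' @export
sim_qc_thresholds <- function() {
  qc_thresholds(genes_min = 300, genes_max = 2950, final_genes_max = 2950,
                gene_min_cells = 12, gene_min_reads = 15,
                lib_min = 3000, lib_max = 300000)
}

# NB detection probability (count > 0)
.p_detect <- function(mu, theta) 1 - (theta / (theta + mu))^theta

# ploidy-wise latent-z densities on a grid; 2n uniform, 4n with constant
# enrichment r below zmax
.z_grid <- function(cfg, n = 41) {
  z <- seq(0, 1, length.out = n)
  r <- cfg$enrichment_4n_cv
  zmax <- cfg$enrichment_zmax
  f4 <- ifelse(z <= zmax, r, (1 - r * zmax) / (1 - zmax))
  w2 <- rep(1 / n, n)
  w4 <- f4 / sum(f4)
  list(z = z, w2 = w2, w4 = w4)
}

# expected detected genes for one hepatocyte ploidy, given per-gene means
# (list with flat mu and zonated mu-by-z matrix) and thetas
.expected_detected <- function(mu_flat, theta_flat, mu_z, theta_z, w) {
  d <- sum(.p_detect(mu_flat, theta_flat))
  if (length(theta_z)) {
    pz <- .p_detect(mu_z, matrix(theta_z, nrow(mu_z), ncol(mu_z)))
    d <- d + sum(as.numeric(pz %*% w))
  }
  d
}

#' Simulate a ploidy-resolved liver snRNA-seq dataset
#'
#' See [sim_config()] for the generative model. Bitwise reproducible for a
#' fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a `CountMatrix`) and `truth` (ground truth:
#'   `nuclei` with latent z / efficiency / stem state, `genes` with class,
#'   slope, DE and module membership, `params` with the calibrated program
#'   effect and planted values, and `panels` with the simulation's cell-type,
#'   zonation and stem panels).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  ## ---- gene table ----------------------------------------------------
  g <- cfg$n_genes
  class_vec <- rep("background", g)
  name_vec <- sprintf("g%04d", seq_len(g))
  cursor <- 0L
  take <- function(n) {
    out <- cursor + seq_len(n)
    cursor <<- cursor + n
    out
  }
  i_stem <- take(length(cfg$stem_markers))
  name_vec[i_stem] <- cfg$stem_markers
  class_vec[i_stem] <- "stem"
  ct_named <- list(hepatocyte = c("Ppara", "Pck1"),
                   hepatobiliary = c("Sspn", "Cmss1"),
                   endothelial = c("Plekhg1", "Stab2", "Ptprb"))
  ct_idx <- list()
  for (ct in c("hepatocyte", names(cfg$n_other))) {
    ii <- take(cfg$n_ct_markers)
    ct_idx[[ct]] <- ii
    nm <- ct_named[[ct]]
    if (!is.null(nm)) name_vec[ii[seq_along(nm)]] <- nm
    class_vec[ii] <- paste0("marker_", ct)
  }
  i_cvp <- take(cfg$panel_size_zonated)
  name_vec[i_cvp[1:4]] <- c("Cyp2e1", "Gsta3", "Cyp27a1", "Mup17")
  class_vec[i_cvp] <- "pericentral_panel"
  i_pvp <- take(cfg$panel_size_zonated)
  name_vec[i_pvp[1:4]] <- c("Alb", "Cyp2f2", "Asl", "Gls2")
  class_vec[i_pvp] <- "periportal_panel"
  i_nzp <- take(cfg$panel_size_nonzon)
  name_vec[i_nzp[1:4]] <- c("Hnf4a", "Ces3a", "Hamp", "Cyp3a25")
  class_vec[i_nzp] <- "non_zonated_panel"
  i_cvx <- take(cfg$n_pericentral - cfg$panel_size_zonated - cfg$n_zon_ploidy_only)
  class_vec[i_cvx] <- "pericentral"
  i_pvx <- take(cfg$n_periportal - cfg$panel_size_zonated - cfg$n_zon_ploidy_only)
  class_vec[i_pvx] <- "periportal"
  i_cv4 <- take(cfg$n_zon_ploidy_only)
  class_vec[i_cv4] <- "pericentral_4n_only"
  i_pv2 <- take(cfg$n_zon_ploidy_only)
  class_vec[i_pv2] <- "periportal_2n_only"
  i_up <- take(cfg$n_deg %/% 2)
  class_vec[i_up] <- "deg_up"
  i_dn <- take(cfg$n_deg - cfg$n_deg %/% 2)
  class_vec[i_dn] <- "deg_down"
  i_prog <- take(cfg$n_program)
  class_vec[i_prog] <- "program"
  i_hk <- take(cfg$n_housekeeping)
  class_vec[i_hk] <- "housekeeping"

  mu <- numeric(g)
  mu[i_stem] <- 0  # stem markers are generated by the latent-state mechanism
  for (ct in names(ct_idx)) {
    mu[ct_idx[[ct]]] <- stats::rlnorm(cfg$n_ct_markers, cfg$ct_mu_meanlog,
                                      cfg$ct_mu_sdlog)
  }
  mu[c(i_cvp, i_pvp, i_nzp)] <- cfg$panel_mu
  mu[c(i_cvx, i_pvx)] <- stats::rlnorm(length(i_cvx) + length(i_pvx),
                                       cfg$zon_mu_meanlog, cfg$zon_mu_sdlog)
  mu[c(i_cv4, i_pv2)] <- stats::rlnorm(length(i_cv4) + length(i_pv2),
                                       cfg$zon_only_mu_meanlog, cfg$zon_only_mu_sdlog)
  mu[c(i_up, i_dn)] <- stats::rlnorm(cfg$n_deg, cfg$deg_mu_meanlog, cfg$deg_mu_sdlog)
  mu[i_prog] <- stats::rlnorm(cfg$n_program, cfg$program_mu_meanlog,
                              cfg$program_mu_sdlog)
  mu[i_hk] <- stats::rlnorm(cfg$n_housekeeping, cfg$hk_mu_meanlog, cfg$hk_mu_sdlog)
  bg <- class_vec == "background"
  mu[bg] <- stats::rlnorm(sum(bg), cfg$bg_mu_meanlog, cfg$bg_mu_sdlog)

  slope <- numeric(g)
  slope[c(i_cvp, i_pvp)] <- cfg$panel_slope
  slope[c(i_cvx, i_pvx)] <- stats::runif(length(i_cvx) + length(i_pvx),
                                         cfg$slope_range[1], cfg$slope_range[2])
  slope[c(i_cv4, i_pv2)] <- cfg$zon_only_slope
  is_cv_gene <- class_vec %in% c("pericentral_panel", "pericentral", "pericentral_4n_only")
  is_pv_gene <- class_vec %in% c("periportal_panel", "periportal", "periportal_2n_only")

  # reference expression context for the gene-wise NB size: own-type level
  # for markers, hepatocyte baseline otherwise
  mu_ref <- mu
  for (ct in names(ct_idx)) mu_ref[ct_idx[[ct]]] <- mu[ct_idx[[ct]]] * cfg$ct_fold
  mu_ref[i_stem] <- cfg$stem_mu
  theta <- pmin(pmax(cfg$theta_coef * mu_ref^cfg$theta_exp, cfg$theta_min),
                cfg$theta_max)
  theta_2n <- theta / cfg$dispersion_ratio_2n

  ## ---- program-effect calibration (expected detected genes) ----------
  grid <- .z_grid(cfg)
  zon <- is_cv_gene | is_pv_gene
  # hepatocyte-context flat means: own markers up, foreign markers down
  mu_hep <- mu
  mu_hep[ct_idx$hepatocyte] <- mu[ct_idx$hepatocyte] * cfg$ct_fold
  for (ct in names(cfg$n_other)) {
    mu_hep[ct_idx[[ct]]] <- mu[ct_idx[[ct]]] * cfg$ct_off
  }
  # z-gradient shapes, normalized to mean 1 under the uniform z law
  shape_z <- function(idx, forward) {
    b <- slope[idx]
    zz <- if (forward) grid$z else 1 - grid$z
    exp(-outer(b, zz)) / ((1 - exp(-b)) / b)
  }
  mu_z_of <- function(pl) {
    # per-gene hepatocyte mean over the z grid for the zonated genes
    m <- matrix(mu_hep[zon], sum(zon), length(grid$z))
    sh <- matrix(1, sum(zon), length(grid$z))
    cls <- class_vec[zon]
    cv_rows <- cls %in% c("pericentral_panel", "pericentral")
    pv_rows <- cls %in% c("periportal_panel", "periportal")
    sh[cv_rows, ] <- shape_z(which(zon)[cv_rows], TRUE)
    sh[pv_rows, ] <- shape_z(which(zon)[pv_rows], FALSE)
    cv4 <- cls == "pericentral_4n_only"
    pv2 <- cls == "periportal_2n_only"
    if (pl == "4n") {
      s <- shape_z(which(zon)[cv4], TRUE)
      sh[cv4, ] <- s / as.numeric(s %*% grid$w4)  # mean 1 under the 4n z law
    } else {
      sh[pv2, ] <- shape_z(which(zon)[pv2], FALSE)
    }
    m * sh
  }
  flat_idx <- which(!zon & !(seq_len(g) %in% i_stem))
  stem_det <- sum(ifelse(cfg$stem_markers %in% cfg$stem_module,
                         cfg$p_stem * cfg$p_module_on +
                           (1 - cfg$p_stem) * cfg$p_module_off,
                         cfg$p_background))
  d2 <- .expected_detected(mu_hep[flat_idx], theta_2n[flat_idx],
                           mu_z_of("2n"), theta_2n[zon], grid$w2) + stem_det
  mu4_flat <- mu_hep[flat_idx]
  mu4_flat[flat_idx %in% i_up] <- mu4_flat[flat_idx %in% i_up] * 2^cfg$deg_log2fc
  mu4_flat[flat_idx %in% i_dn] <- mu4_flat[flat_idx %in% i_dn] * 2^(-cfg$deg_log2fc)
  prog_in_flat <- flat_idx %in% i_prog
  d4_fixed <- .expected_detected(mu4_flat[!prog_in_flat],
                                 theta[flat_idx][!prog_in_flat],
                                 mu_z_of("4n"), theta[zon], grid$w4) + stem_det
  prog_detect <- function(e) {
    sum(.p_detect(e * mu4_flat[prog_in_flat], theta[flat_idx][prog_in_flat]))
  }
  target <- cfg$detection_fold * d2
  h <- function(e) d4_fixed + prog_detect(e) - target
  if (h(1) >= 0) {
    e_prog <- 1
  } else if (h(5000) < 0) {
    stop("infeasible config: detection_fold unreachable with this program size")
  } else {
    e_prog <- stats::uniroot(h, c(1, 5000), tol = 1e-8)$root
  }

  ## ---- nucleus table --------------------------------------------------
  types <- c(rep("hepatocyte", cfg$n_hep_2n + cfg$n_hep_4n),
             rep(names(cfg$n_other), cfg$n_other))
  ploidy <- c(rep("2n", cfg$n_hep_2n), rep("4n", cfg$n_hep_4n),
              rep("2n", sum(cfg$n_other)))
  n <- length(types)
  plate <- sprintf("P%02d", (seq_len(n) - 1L) %% cfg$n_plates + 1L)
  animal <- sprintf("M%02d", (seq_len(n) - 1L) %% cfg$n_animals + 1L)
  dil_names <- names(cfg$dilution_groups)
  plate_dil <- dil_names[((seq_len(cfg$n_plates) - 1L) %% length(dil_names)) + 1L]
  dil <- plate_dil[as.integer(sub("P", "", plate))]
  eff <- stats::rlnorm(n, 0, cfg$efficiency_sdlog)
  stratified_z <- function(nn, density4) {
    zmax <- cfg$enrichment_zmax
    frac_low <- if (density4) cfg$enrichment_4n_cv * zmax else zmax
    n_low <- round(nn * frac_low)
    zz <- c(stats::runif(n_low, 0, zmax), stats::runif(nn - n_low, zmax, 1))
    sample(zz)
  }
  z <- rep(NA_real_, n)
  z[ploidy == "2n" & types == "hepatocyte"] <- stratified_z(cfg$n_hep_2n, FALSE)
  z[ploidy == "4n"] <- stratified_z(cfg$n_hep_4n, TRUE)
  stem_state <- rep(0L, n)
  is_hep <- types == "hepatocyte"
  stem_state[is_hep] <- stats::rbinom(sum(is_hep), 1L, cfg$p_stem)
  tech <- rep(FALSE, n)
  if (cfg$n_tech_replicates > 0) tech[seq_len(cfg$n_tech_replicates)] <- TRUE

  ## ---- mean matrix -----------------------------------------------------
  M <- outer(eff, mu)
  for (ct in names(ct_idx)) {
    own <- types == ct
    M[own, ct_idx[[ct]]] <- M[own, ct_idx[[ct]]] * cfg$ct_fold
    M[!own, ct_idx[[ct]]] <- M[!own, ct_idx[[ct]]] * cfg$ct_off
  }
  hep_specific <- is_cv_gene | is_pv_gene | class_vec == "non_zonated_panel"
  M[!is_hep, hep_specific] <- M[!is_hep, hep_specific] * cfg$ct_off
  # zonation gradients within hepatocytes
  grad <- function(idx, zz, forward, norm_w = NULL, norm_z = NULL) {
    b <- slope[idx]
    arg <- if (forward) zz else 1 - zz
    raw <- exp(-outer(zz * 0 + arg, b))  # nuclei x genes
    if (is.null(norm_w)) {
      A <- (1 - exp(-b)) / b  # uniform-z mean of exp(-b z)
    } else {
      zg <- if (forward) norm_z else 1 - norm_z
      A <- as.numeric(exp(-outer(b, zg)) %*% norm_w)
    }
    sweep(raw, 2L, A, "/")
  }
  hz <- z[is_hep]
  cv_main <- c(i_cvp, i_cvx)
  pv_main <- c(i_pvp, i_pvx)
  M[is_hep, cv_main] <- M[is_hep, cv_main] * grad(cv_main, hz, TRUE)
  M[is_hep, pv_main] <- M[is_hep, pv_main] * grad(pv_main, hz, FALSE)
  hep4 <- is_hep & ploidy == "4n"
  hep2 <- is_hep & ploidy == "2n"
  # zonated only in one ploidy, mean-matched in the other
  M[hep4, i_cv4] <- M[hep4, i_cv4] *
    grad(i_cv4, z[hep4], TRUE, norm_w = grid$w4, norm_z = grid$z)
  M[hep2, i_pv2] <- M[hep2, i_pv2] * grad(i_pv2, z[hep2], FALSE)
  # strong DEGs and the calibrated 4n program
  M[hep4, i_up] <- M[hep4, i_up] * 2^cfg$deg_log2fc
  M[hep4, i_dn] <- M[hep4, i_dn] * 2^(-cfg$deg_log2fc)
  M[hep4, i_prog] <- M[hep4, i_prog] * e_prog

  TH <- matrix(theta, n, g, byrow = TRUE)
  TH[ploidy == "2n", ] <- matrix(theta_2n, sum(ploidy == "2n"), g, byrow = TRUE)
  counts <- matrix(stats::rnbinom(n * g, size = TH, mu = M), n, g)

  ## ---- stem markers: shared latent Bernoulli factor --------------------
  for (k in seq_along(i_stem)) {
    gene <- i_stem[k]
    in_module <- cfg$stem_markers[k] %in% cfg$stem_module
    p_on <- rep(0, n)
    p_on[is_hep] <- if (in_module) {
      ifelse(stem_state[is_hep] == 1L, cfg$p_module_on, cfg$p_module_off)
    } else {
      cfg$p_background
    }
    on <- stats::rbinom(n, 1L, p_on)
    counts[, gene] <- on * (1L + stats::rnbinom(n, size = 2,
                                                mu = pmax(cfg$stem_mu * eff - 1, 0.1)))
  }
  # Epcam doubles as a hepatobiliary epithelial marker
  if ("Epcam" %in% cfg$stem_markers && "hepatobiliary" %in% types) {
    gene <- i_stem[match("Epcam", cfg$stem_markers)]
    hb <- types == "hepatobiliary"
    counts[hb, gene] <- stats::rnbinom(sum(hb), size = 2,
                                       mu = cfg$ct_fold * 2 * eff[hb])
  }

  ## ---- ERCC spike-ins --------------------------------------------------
  ercc <- ercc_concentrations()
  conc <- ercc$concentration / sum(ercc$concentration)
  dil_factor <- cfg$dilution_groups[dil]
  mu_ercc <- outer(eff * as.numeric(dil_factor) * cfg$ercc_total_base, conc)
  ercc_mat <- matrix(stats::rpois(n * nrow(ercc), mu_ercc), n, nrow(ercc))

  ## ---- assembly --------------------------------------------------------
  feature_id <- sprintf("G%05d", seq_len(g))
  lengths_kb <- stats::rlnorm(g, log(2.5), 0.6)
  features <- data.frame(
    feature_id = c(feature_id, ercc$ercc_id),
    gene_name = c(name_vec, ercc$ercc_id),
    is_ercc = c(rep(FALSE, g), rep(TRUE, nrow(ercc))),
    length_kb = c(lengths_kb, ercc$length / 1000),
    stringsAsFactors = FALSE)
  nuclei <- data.frame(
    nucleus_id = sprintf("N%04d", seq_len(n)),
    ploidy = ploidy, plate_id = plate, animal_id = animal,
    dilution_group = dil, is_technical_replicate = tech,
    stringsAsFactors = FALSE)
  cm <- count_matrix(cbind(counts, ercc_mat), features, nuclei)

  gene_truth <- data.frame(
    feature_id = feature_id, gene_name = name_vec, class = class_vec,
    mu_base = mu, theta_4n = theta, theta_2n = theta_2n,
    zonation_slope = ifelse(is_cv_gene, -slope, ifelse(is_pv_gene, slope, 0)),
    is_ploidy_de = class_vec %in% c("deg_up", "deg_down", "program"),
    ploidy_log2fc = ifelse(class_vec == "deg_up", cfg$deg_log2fc,
                    ifelse(class_vec == "deg_down", -cfg$deg_log2fc,
                    ifelse(class_vec == "program", log2(e_prog), 0))),
    is_module = name_vec %in% cfg$stem_module,
    stringsAsFactors = FALSE)
  nuc_truth <- data.frame(
    nucleus_id = nuclei$nucleus_id, cell_type = types, ploidy = ploidy,
    z = z, efficiency = eff, stem_state = stem_state,
    stringsAsFactors = FALSE)
  panels <- list(
    celltype = list(hepatocyte = c("Cyp27a1", "Ppara", "Pck1"),
                    hepatobiliary = c("Sspn", "Cmss1", "Epcam"),
                    endothelial = c("Plekhg1", "Stab2", "Ptprb")),
    zonation = list(pericentral = name_vec[i_cvp],
                    periportal = name_vec[i_pvp],
                    non_zonated = name_vec[i_nzp]),
    stem_markers = cfg$stem_markers, stem_module = cfg$stem_module)
  params <- list(detection_fold = cfg$detection_fold,
                 program_effect = e_prog,
                 expected_detected_2n = d2,
                 expected_detected_4n = d4_fixed + prog_detect(e_prog),
                 enrichment_4n_cv = cfg$enrichment_4n_cv,
                 dispersion_ratio_2n = cfg$dispersion_ratio_2n,
                 seed = cfg$seed)
  list(matrix = cm,
       truth = list(nuclei = nuc_truth, genes = gene_truth,
                    panels = panels, params = params))
}

#' The packaged synthetic ERCC concentration ladder
#'
#' 92 spike-in species across 23 two-fold concentration levels (4 species per
#' level), mimicking the dynamic range of the standard ERCC mix. This is a
#' synthetic stand-in for the vendor concentration sheet; only relative
#' abundances matter for size-factor work.
#'
#' @return data.frame with `ercc_id`, `concentration` (relative),
#'   `length` (nt).
#' @export
ercc_concentrations <- function() {
  path <- system.file("extdata", "ercc_concentrations_synthetic.tsv",
                      package = "hepnuc")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Closed-form expectations for a simulation configuration
#'
#' Deterministic summaries used as independent oracles for the sampled data:
#' expected mean expression by gene class, expected ERCC totals and ratios by
#' dilution group, expected pericentral-half occupancy by ploidy, the planted
#' detection fold and the expected relative zonation profile of a panel gene
#' along binned z.
#'
#' @param cfg a [sim_config()].
#' @param n_bins bins for the expected zonation profiles (default 10).
#' @return named list of expectation tables.
#' @export
expected_summaries <- function(cfg, n_bins = 10) {
  stopifnot(inherits(cfg, "sim_config"))
  lnorm_mean <- function(ml, sl) exp(ml + sl^2 / 2)
  class_means <- data.frame(
    class = c("background", "housekeeping", "program_2n", "deg", "zonated",
              "celltype_marker_own", "panel"),
    expected_mu = c(lnorm_mean(cfg$bg_mu_meanlog, cfg$bg_mu_sdlog),
                    lnorm_mean(cfg$hk_mu_meanlog, cfg$hk_mu_sdlog),
                    lnorm_mean(cfg$program_mu_meanlog, cfg$program_mu_sdlog),
                    lnorm_mean(cfg$deg_mu_meanlog, cfg$deg_mu_sdlog),
                    lnorm_mean(cfg$zon_mu_meanlog, cfg$zon_mu_sdlog),
                    cfg$ct_fold * lnorm_mean(cfg$ct_mu_meanlog, cfg$ct_mu_sdlog),
                    cfg$panel_mu),
    stringsAsFactors = FALSE)
  eff_mean <- exp(cfg$efficiency_sdlog^2 / 2)
  ercc <- data.frame(
    dilution_group = names(cfg$dilution_groups),
    relative_amount = as.numeric(cfg$dilution_groups),
    expected_total = eff_mean * as.numeric(cfg$dilution_groups) * cfg$ercc_total_base,
    stringsAsFactors = FALSE)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  b <- cfg$panel_slope
  A <- if (b == 0) 1 else (1 - exp(-b)) / b
  # expected endogenous reads of a 2n hepatocyte at capture efficiency 1
  n_structured <- length(cfg$stem_markers) + 3 * cfg$n_ct_markers +
    2 * cfg$panel_size_zonated + cfg$panel_size_nonzon +
    (cfg$n_pericentral - cfg$panel_size_zonated) +
    (cfg$n_periportal - cfg$panel_size_zonated) +
    cfg$n_deg + cfg$n_program + cfg$n_housekeeping
  n_bg <- cfg$n_genes - n_structured
  e_ct <- lnorm_mean(cfg$ct_mu_meanlog, cfg$ct_mu_sdlog)
  stem_p <- ifelse(cfg$stem_markers %in% cfg$stem_module,
                   cfg$p_stem * cfg$p_module_on +
                     (1 - cfg$p_stem) * cfg$p_module_off,
                   cfg$p_background)
  endo_total_2n_hep <-
    n_bg * lnorm_mean(cfg$bg_mu_meanlog, cfg$bg_mu_sdlog) +
    cfg$n_housekeeping * lnorm_mean(cfg$hk_mu_meanlog, cfg$hk_mu_sdlog) +
    cfg$n_program * lnorm_mean(cfg$program_mu_meanlog, cfg$program_mu_sdlog) +
    cfg$n_deg * lnorm_mean(cfg$deg_mu_meanlog, cfg$deg_mu_sdlog) +
    (2 * cfg$panel_size_zonated + cfg$panel_size_nonzon) * cfg$panel_mu +
    (cfg$n_pericentral + cfg$n_periportal - 2 * cfg$panel_size_zonated -
       2 * cfg$n_zon_ploidy_only) * lnorm_mean(cfg$zon_mu_meanlog, cfg$zon_mu_sdlog) +
    2 * cfg$n_zon_ploidy_only * lnorm_mean(cfg$zon_only_mu_meanlog,
                                           cfg$zon_only_mu_sdlog) +
    cfg$n_ct_markers * cfg$ct_fold * e_ct +
    2 * cfg$n_ct_markers * cfg$ct_off * e_ct +
    sum(stem_p) * cfg$stem_mu
  list(class_means = class_means,
       ercc = ercc,
       expected_endo_total_2n_hep = endo_total_2n_hep,
       cv_half_fraction = c(`2n` = 0.5, `4n` = cfg$enrichment_4n_cv * 0.5),
       planted_enrichment = cfg$enrichment_4n_cv,
       planted_detection_fold = cfg$detection_fold,
       profile_pericentral = exp(-b * mids) / A,
       profile_periportal = exp(-b * (1 - mids)) / A)
}
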