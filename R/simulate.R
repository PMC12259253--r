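#' Synthetic two-group IMC cohort: configuration
#'
#' Defines the generative model for a two-group cohort of tumor-tissue ROIs
#' emulating the structure the pipeline's analyses assume: compact CK+ tumor
#' nests (unions of overlapping disks) surrounded by stroma holding CD4/CD8
#' T cells, CD68+ macrophages (TAM) and CD20+ B cells; group-dependent
#' shifts in functional-marker intensity; and a group-dependent spatial
#' exclusion shift that pushes immune cells farther from the nest boundary
#' in the first ("HIV-like") group.
#'
#' Intensities are on an integer "ion count" scale: each cell draws a
#' lognormal per-cell mean for every marker it expresses (`meanlog =
#' log(mean) - noise_sd^2/2` so the configured value is the expected
#' count), and rendering adds per-pixel Poisson counts around that mean on
#' top of a Poisson background. Immune cells are placed at a distance from
#' the nest boundary drawn from a gamma base distribution plus the group's
#' exclusion shift, under a hard-core minimum nucleus separation.
#'
#' @param n_cases_per_group cases per group (the emulated study had 18/19).
#' @param groups two group labels; the first is the HIV-like group (fold
#'   change numerator, positive exclusion shift).
#' @param rois_per_case ROIs (tissue cores) per case.
#' @param roi_size_px `c(H, W)` ROI size in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param cell_counts named counts per ROI for populations `tumor`, `CD4T`,
#'   `CD8T`, `TAM`, `B` (zero allowed).
#' @param marker_effects data.frame with columns `population`, `marker`, and
#'   one expected-count column per group (see [default_marker_effects()]).
#'   Optional `frac_<group>` columns give the fraction of the population's
#'   cells expressing the marker (default 1 = all), and optional
#'   `grad_<group>` columns a tumor-proximity gradient strength (expressing
#'   cells' mean is damped by `exp(-grad * dist_to_nest / 25 um)`; 0 =
#'   spatially flat). Mean columns set the intensity scale seen by per-cell
#'   statistics; positive-fraction and gradient differences additionally
#'   reshape a marker's spatial concentration across the tissue, which is
#'   what patch-profile (SSD) analyses detect.
#' @param exclusion_shift_um named per-group extra immune-to-nest distance.
#' @param base_distance_shape,base_distance_scale_um gamma parameters of the
#'   baseline immune-to-nest boundary distance (defaults mean 25 um: TILs
#'   and TAMs populate the stroma adjacent to the nests).
#' @param noise_sd lognormal `sdlog` of per-cell mean intensities.
#' @param background_rate per-pixel Poisson background count rate.
#' @param nucleus_radius_px rendered nuclear disk radius.
#' @param signal_radius_px rendered membrane/cytoplasm disk radius for
#'   lineage and functional markers.
#' @param min_center_dist_px hard-core minimum distance between nuclei.
#' @param n_nests,nest_radius_px tumor nest count and disk radius.
#' @param lineage_mean,nuclear_mean expected counts of lineage and nuclear
#'   marker signal.
#' @param panel a [panel_config()]; defaults to [default_panel()].
#' @param seed master seed; per-case seeds are derived deterministically.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cases_per_group = 18,
                              groups = c("PWH", "PWOH"),
                              rois_per_case = 1,
                              roi_size_px = c(256, 256),
                              pixel_size_um = 1,
                              cell_counts = c(tumor = 80, CD4T = 30, CD8T = 30,
                                              TAM = 25, B = 15),
                              marker_effects = default_marker_effects(groups),
                              exclusion_shift_um = stats::setNames(c(15, 0), groups),
                              base_distance_shape = 2,
                              base_distance_scale_um = 12.5,
                              noise_sd = 0.5,
                              background_rate = 0.2,
                              nucleus_radius_px = 3,
                              signal_radius_px = 4,
                              min_center_dist_px = 8,
                              n_nests = 2,
                              nest_radius_px = 55,
                              lineage_mean = 50,
                              nuclear_mean = 80,
                              panel = default_panel(pixel_size_um),
                              seed = 1) {
  stopifnot(length(groups) == 2L, is_count(n_cases_per_group),
            is_count(rois_per_case), rois_per_case >= 1,
            length(roi_size_px) == 2L, all(roi_size_px >= 32),
            noise_sd > 0, background_rate >= 0,
            nucleus_radius_px >= 1, signal_radius_px >= nucleus_radius_px,
            min_center_dist_px >= 1)
  if (any(cell_counts < 0) || !all(names(cell_counts) %in% sim_populations()))
    stopf("cell_counts must be non-negative and named among: %s",
          paste(sim_populations(), collapse = ", "))
  if (!all(groups %in% names(exclusion_shift_um)))
    stopf("exclusion_shift_um must be named by group")
  if (!all(c("population", "marker", groups) %in% names(marker_effects)))
    stopf("marker_effects needs columns population, marker, and one per group")
  structure(list(
    n_cases_per_group = n_cases_per_group, groups = groups,
    rois_per_case = rois_per_case, roi_size_px = roi_size_px,
    pixel_size_um = pixel_size_um, cell_counts = cell_counts,
    marker_effects = marker_effects, exclusion_shift_um = exclusion_shift_um,
    base_distance_shape = base_distance_shape,
    base_distance_scale_um = base_distance_scale_um,
    noise_sd = noise_sd, background_rate = background_rate,
    nucleus_radius_px = nucleus_radius_px, signal_radius_px = signal_radius_px,
    min_center_dist_px = min_center_dist_px,
    n_nests = n_nests, nest_radius_px = nest_radius_px,
    lineage_mean = lineage_mean, nuclear_mean = nuclear_mean,
    panel = panel, seed = seed), class = "simulation_config")
}

sim_populations <- function() c("tumor", "CD4T", "CD8T", "TAM", "B")

# Lineage markers rendered for each population.
population_lineage <- function() {
  list(tumor = "CK", CD4T = c("CD3", "CD4"), CD8T = c("CD3", "CD8"),
       TAM = "CD68", B = "CD20")
}

#' Default group-dependent functional marker effects
#'
#' Expected per-cell counts per (population, marker), one column per group.
#' Where the emulated study printed random-intercept group means (e.g. KI67
#' 1.62 vs 0.53 on CD8 T cells; PD-L2 0.30 vs 0.20 on TAMs) the defaults are
#' those values scaled by 100 to the count scale; remaining functional
#' markers get moderate values with the reported direction (elevated PD-1 /
#' LAG3 / KI67 / CD25 / GRZB on T cells and PD-L1 / PD-L2 / B7-H3 / B7-H4 /
#' VISTA / IDO1 / B2M on TAMs in the HIV-like first group).
#'
#' @param groups two group labels (first = HIV-like).
#' @return data.frame with columns `population`, `marker`, `<group1>`,
#'   `<group2>`.
#' @export
default_marker_effects <- function(groups = c("PWH", "PWOH")) {
  e <- rbind(
    data.frame(population = "CD8T",
               marker = c("KI67", "GRZB", "PD1", "LAG3", "CD25", "TIM3",
                          "TBET", "CD45RO", "FOXP3"),
               g1 = c(162, 55, 27, 30, 50, 25, 60, 100, 5),
               g2 = c(53, 42, 18, 20, 35, 20, 45, 70, 5)),
    data.frame(population = "CD4T",
               marker = c("PD1", "KI67", "LAG3", "CD25", "TBET", "CD45RO",
                          "FOXP3", "GRZB", "TIM3"),
               g1 = c(34, 160, 28, 55, 50, 90, 12, 20, 18),
               g2 = c(19, 56, 19, 38, 40, 90, 12, 20, 18)),
    data.frame(population = "TAM",
               marker = c("PDL1", "PDL2", "KI67", "B7H3", "B7H4", "VISTA",
                          "IDO1", "B2M"),
               g1 = c(16, 30, 143, 40, 30, 50, 35, 120),
               g2 = c(11, 20, 36, 25, 20, 30, 22, 90)),
    data.frame(population = "tumor",
               marker = c("B2M", "PDL1", "PDL2", "KI67"),
               g1 = c(80, 20, 15, 60), g2 = c(80, 20, 15, 60)),
    data.frame(population = "B", marker = "KI67", g1 = 30, g2 = 30))
  names(e)[3:4] <- groups
  e
}

#' Planted-effect study configuration
#'
#' A [simulation_config()] in which every group difference is removed
#' except a planted positive-fraction and intensity effect on the given
#' markers: in the HIV-like group a fraction `frac_high` of the expressing
#' populations' cells carry the marker at `mean_factor` times the baseline
#' count, versus `frac_low` in the control group; spatial exclusion is
#' switched off. Used for recovery studies of the spectral classifier and
#' the marker ranking.
#'
#' @param markers markers to plant the effect on (must appear in
#'   [default_marker_effects()]).
#' @param n_cases_per_group cases per group.
#' @param mean_factor intensity multiplier in the HIV-like group.
#' @param frac_high,frac_low expressing fractions in the HIV-like and
#'   control groups.
#' @param seed master seed.
#' @param ... further arguments to [simulation_config()].
#' @return A [simulation_config()].
#' @export
planted_effect_config <- function(markers = c("PD1", "CD25", "PDL2"),
                                  n_cases_per_group = 20, mean_factor = 8,
                                  frac_high = 0.95, frac_low = 0.05,
                                  seed = 1, ...) {
  groups <- c("PWH", "PWOH")
  eff <- null_marker_effects(default_marker_effects(groups), groups)
  sel <- eff$marker %in% markers
  if (!any(sel)) stopf("no marker-effect rows match: %s", paste(markers, collapse = ", "))
  eff[[groups[1L]]][sel] <- eff[[groups[1L]]][sel] * mean_factor
  eff[[paste0("frac_", groups[1L])]] <- ifelse(sel, frac_high, 1)
  eff[[paste0("frac_", groups[2L])]] <- ifelse(sel, frac_low, 1)
  simulation_config(n_cases_per_group = n_cases_per_group, groups = groups,
                    marker_effects = eff,
                    exclusion_shift_um = stats::setNames(c(0, 0), groups),
                    seed = seed, ...)
}

#' Null variant of a marker-effect table
#'
#' Sets both group columns to their row-wise mean, removing every group
#' effect (used for type-I-error calibration).
#'
#' @param effects a marker-effect data.frame.
#' @param groups the two group column names.
#' @return The equalized data.frame.
#' @export
null_marker_effects <- function(effects, groups = c("PWH", "PWOH")) {
  m <- rowMeans(effects[, groups])
  effects[[groups[1L]]] <- m
  effects[[groups[2L]]] <- m
  effects
}

# Distance (px) from every pixel to the nest boundary: negative inside the
# nest union, positive in stroma. Nests are disks, so the distance to the
# union has the closed form min_k(|x - c_k| - r_k).
nest_distance_map <- function(H, W, nests) {
  y <- matrix(0:(H - 1L), H, W)
  x <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  D <- matrix(Inf, H, W)
  for (k in seq_len(nrow(nests)))
    D <- pmin(D, sqrt((x - nests$x[k])^2 + (y - nests$y[k])^2) - nests$r[k])
  D
}

#' Generate one synthetic ROI with ground truth
#'
#' Places tumor cells inside the nest union and immune cells in the stroma
#' at gamma-plus-shift distances from the nest boundary (hard-core
#' rejection sampling), draws per-cell lognormal marker means, and (unless
#' `render = FALSE`) renders the multichannel image: nuclear disks on the
#' nuclear channels, membrane/cytoplasm disks for the population's lineage
#' markers and its functional markers, per-pixel Poisson counts around each
#' cell mean plus Poisson background everywhere.
#'
#' @param config a [simulation_config()].
#' @param case_id,roi_id identifiers.
#' @param group group label (must be one of `config$groups`).
#' @param seed integer seed for this ROI.
#' @param render if `FALSE`, skip image rendering and return the truth
#'   table only (fast path for statistical calibration studies).
#' @return list with `image` (a [multichannel_image()] or `NULL`) and
#'   `truth` (a [cell_table()] with `population` labels and a
#'   `dist_to_nest_um` column; tumor cells have negative boundary distance).
#' @export
generate_case_image <- function(config, case_id, group, seed, roi_id = "r1",
                                render = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!group %in% config$groups) stopf("unknown group '%s'", group)
  set.seed(as.integer(seed %% .Machine$integer.max))
  H <- config$roi_size_px[1L]; W <- config$roi_size_px[2L]
  margin <- config$signal_radius_px
  panel <- config$panel
  markers <- panel_marker_names(panel)

  # tumor nests
  nr <- config$nest_radius_px
  lo <- max(nr * 0.5, margin); hiy <- H - 1 - lo; hix <- W - 1 - lo
  if (hix <= lo || hiy <= lo) stopf("ROI too small for the configured nests")
  counts <- config$cell_counts
  counts <- counts[counts > 0]
  inside <- matrix(FALSE, H, W)
  inside[(margin + 1L):(H - margin), (margin + 1L):(W - margin)] <- TRUE
  n_tumor <- if ("tumor" %in% names(counts)) counts[["tumor"]] else 0L
  # candidate pixels needed per tumor cell so hard-core sequential
  # placement stays safely below the random-packing jamming density
  need <- ceiling(1.25 * pi * (config$min_center_dist_px / 2)^2 / 0.547)
  for (attempt in seq_len(50L)) {
    nests <- data.frame(x = stats::runif(config$n_nests, lo, hix),
                        y = stats::runif(config$n_nests, lo, hiy),
                        r = nr * stats::runif(config$n_nests, 0.85, 1.15))
    D <- nest_distance_map(H, W, nests)
    tumor_cand <- which(D <= -2 & inside)
    if (length(tumor_cand) >= need * n_tumor) break
    if (attempt == 50L)
      stopf("infeasible packing: nest area too small for %d tumor cells", n_tumor)
  }
  hard2 <- config$min_center_dist_px^2
  stroma_cand <- which(D >= 1 & inside)

  px <- config$pixel_size_um
  shift_px <- config$exclusion_shift_um[[group]] / px
  shp <- config$base_distance_shape
  scl <- config$base_distance_scale_um / px
  dmax <- max(D[stroma_cand], 1)

  placed_x <- numeric(0); placed_y <- numeric(0)
  pop_out <- character(0); dist_out <- numeric(0)
  place_one <- function(cand_idx) {
    # returns index or NA; honors hard-core against already placed cells
    for (t in seq_len(600L)) {
      i <- cand_idx[sample.int(length(cand_idx), 1L)]
      cy <- (i - 1L) %% H; cx <- (i - 1L) %/% H   # 0-based row/col
      if (!length(placed_x) ||
          min((placed_x - cx)^2 + (placed_y - cy)^2) >= hard2) {
        placed_x <<- c(placed_x, cx); placed_y <<- c(placed_y, cy)
        return(i)
      }
    }
    NA_integer_
  }

  for (pop in names(counts)) {
    for (j in seq_len(counts[[pop]])) {
      if (pop == "tumor") {
        i <- place_one(tumor_cand)
        if (is.na(i)) stopf("infeasible packing: could not place tumor cell %d", j)
      } else {
        i <- NA_integer_
        for (draw in seq_len(60L)) {
          d_target <- min(stats::rgamma(1L, shape = shp, scale = scl) + shift_px,
                          dmax - 0.5)
          cand <- stroma_cand[abs(D[stroma_cand] - d_target) <= 1.5]
          if (!length(cand)) next
          i <- place_one(cand)
          if (!is.na(i)) break
        }
        if (is.na(i)) stopf("infeasible packing: could not place %s cell %d", pop, j)
      }
      pop_out <- c(pop_out, pop)
      dist_out <- c(dist_out, D[i])
    }
  }
  n <- length(pop_out)

  # per-cell expected marker counts (signal only; background is added at render)
  mu <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  lin <- population_lineage()
  eff <- config$marker_effects
  sdl <- config$noise_sd
  draw_mean <- function(m) stats::rlnorm(1L, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
  for (i in seq_len(n)) {
    pop <- pop_out[i]
    for (m in c("DNA", "H3"))
      if (m %in% markers) mu[i, m] <- draw_mean(config$nuclear_mean)
    for (m in intersect(lin[[pop]], markers))
      mu[i, m] <- draw_mean(config$lineage_mean)
    rows <- which(eff$population == pop & eff$marker %in% markers)
    fcol <- paste0("frac_", group)
    gcol <- paste0("grad_", group)
    for (r in rows) {
      v <- eff[[group]][r]
      fr <- if (fcol %in% names(eff)) eff[[fcol]][r] else 1
      gr <- if (gcol %in% names(eff)) eff[[gcol]][r] else 0
      if (v > 0 && (fr >= 1 || stats::runif(1L) < fr)) {
        m_i <- draw_mean(v)
        # tumor-proximity gradient: expression decays with distance to the
        # nest boundary on a 25 um length scale, strength gr (0 = flat)
        if (gr != 0) m_i <- m_i * exp(-gr * max(dist_out[i], 0) * px / 25)
        mu[i, eff$marker[r]] <- m_i
      }
    }
  }

  nuc_off <- disk_offsets(config$nucleus_radius_px)
  truth <- cell_table(data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    case_id = case_id, roi_id = roi_id,
    x_px = placed_x, y_px = placed_y,
    area_px = nrow(nuc_off),
    population = pop_out, cluster = NA_integer_,
    mu, check.names = FALSE,
    dist_to_nest_um = dist_out * px), markers)

  image <- NULL
  if (render) {
    sig_off <- disk_offsets(config$signal_radius_px)
    arr <- array(stats::rpois(H * W * length(markers), config$background_rate),
                 c(H, W, length(markers)))
    nuclear <- markers %in% panel$markers$name[panel$markers$role == "nuclear"]
    HW <- H * W
    for (i in seq_len(n)) {
      r0 <- placed_y[i] + 1L; c0 <- placed_x[i] + 1L
      nuc_idx <- (r0 + nuc_off$di) + (c0 + nuc_off$dj - 1L) * H
      sig_idx <- (r0 + sig_off$di) + (c0 + sig_off$dj - 1L) * H
      for (mi in which(mu[i, ] > 0)) {
        idx <- if (nuclear[mi]) nuc_idx else sig_idx
        arr[idx + (mi - 1L) * HW] <- arr[idx + (mi - 1L) * HW] +
          stats::rpois(length(idx), mu[i, mi])
      }
    }
    image <- multichannel_image(arr, markers, case_id = case_id, roi_id = roi_id,
                                pixel_size_um = px)
  }
  list(image = image, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' `n_cases_per_group` cases per group, each with `rois_per_case` ROIs;
#' per-ROI seeds are drawn deterministically from the master seed so the
#' whole cohort is reproducible bit for bit.
#'
#' @param config a [simulation_config()].
#' @param render render images (`FALSE` returns ground-truth tables only).
#' @return An object of class `synthetic_cohort`: list with `manifest`
#'   (a [cohort_manifest()]), `images` (named list, possibly of `NULL`s),
#'   `truth` (combined [cell_table()]) and `config`.
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(config$seed %% .Machine$integer.max))
  n <- config$n_cases_per_group
  case_id <- as.vector(vapply(config$groups, function(g)
    sprintf("%s_%02d", g, seq_len(n)), character(n)))
  group <- rep(config$groups, each = n)
  n_roi <- config$rois_per_case
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, length(case_id) * n_roi),
                  nrow = length(case_id))
  manifest <- cohort_manifest(data.frame(case_id = case_id, group = group))
  images <- list(); truth <- vector("list", length(case_id) * n_roi)
  k <- 0L
  for (i in seq_along(case_id)) {
    for (r in seq_len(n_roi)) {
      k <- k + 1L
      out <- generate_case_image(config, case_id[i], group[i], seeds[i, r],
                                 roi_id = sprintf("r%d", r), render = render)
      images[[sprintf("%s_r%d", case_id[i], r)]] <- out$image
      truth[[k]] <- out$truth
    }
  }
  all_truth <- do.call(rbind, lapply(truth, as.data.frame))
  structure(list(manifest = manifest, images = images,
                 truth = cell_table(all_truth, panel_marker_names(config$panel)),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases (%s), %d ROIs, %d truth cells\n",
              nrow(x$manifest), paste(table(x$manifest$group), collapse = "+"),
              length(x$images), nrow(x$truth)))
  invisible(x)
}

#' Ground-truth summary of a synthetic cohort
#'
#' Computed from the truth tables only (never from rendered images): per
#' (population, marker) mean true intensity by group, and the per-group
#' mean immune-to-nest boundary distance. Populations absent from a group
#' are reported as `NA`, not zero.
#'
#' @param cohort a [generate_cohort()] result.
#' @return list with data.frames `marker_means` (population, marker, one
#'   column per group) and `immune_distance` (group, mean_dist_um, n).
#' @export
truth_summary <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- as.data.frame(cohort$truth)
  if (nrow(truth) == 0L) stopf("empty cohort")
  g <- cell_groups(cohort$truth, cohort$manifest)
  markers <- cell_table_markers(cohort$truth)
  groups <- cohort$config$groups
  pops <- unique(cohort$config$marker_effects$population)
  grid <- expand.grid(population = sort(unique(c(pops, truth$population))),
                      marker = markers, stringsAsFactors = FALSE)
  for (gr in groups) {
    grid[[gr]] <- mapply(function(p, m) {
      v <- truth[[m]][truth$population == p & g == gr]
      if (!length(v)) NA_real_ else mean(v)
    }, grid$population, grid$marker)
  }
  imm <- truth$population != "tumor"
  immune_distance <- do.call(rbind, lapply(groups, function(gr) {
    v <- truth$dist_to_nest_um[imm & g == gr]
    data.frame(group = gr,
               mean_dist_um = if (length(v)) mean(v) else NA_real_,
               n = length(v))
  }))
  list(marker_means = grid, immune_distance = immune_distance)
}
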