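#' Configuration for the synthetic MINFLUX/DNA-PAINT generator
#'
#' Describes a simulated field of triple-bladed (trimeric) channels imaged
#' by 3D-MINFLUX with DNA-PAINT labelling. Each trimer is an equilateral
#' triangle of blade-tip label sites whose side length is drawn from a
#' truncated normal conformational distribution; each labelled site emits
#' repeated binding traces of noisy localizations. Generation starts at the
#' "valid localization" level — no photophysics or iteration-level
#' simulation.
#'
#' @param n_trimers Number of trimers placed in the field.
#' @param field_size x/y extent of the field in nm. `NULL` scales the field
#'   with `sqrt(n_trimers)` so that isolated placement stays feasible.
#' @param interblade_mean,interblade_sd Mean and SD (nm) of the
#'   conformational distribution of triangle side lengths; draws are
#'   truncated to (0, 40] nm, the physically possible range between two
#'   blade-tip tags.
#' @param label_efficiency Probability that a protomer carries a functional
#'   label. The real-sample value is unreported; 0.8 is a realistic default
#'   for nanobody labelling and is a free parameter.
#' @param traces_per_label Mean of the per-label trace-count distribution
#'   (Poisson with floor 1: a labelled protomer produces at least one
#'   binding event).
#' @param locs_per_trace Mean of the per-trace localization-count
#'   distribution (Poisson with floor 3, so traces survive the minimum-size
#'   filter and the filter path is exercised rather than starved).
#' @param loc_sd Per-axis localization noise SD in nm.
#' @param linkage_sd Per-axis SD (nm) of the isotropic 3D label offset
#'   (nanobody + docking strand linkage error). The default 1.5 nm/axis
#'   gives a mean 3D displacement of about 2.4 nm.
#' @param z_plane_sd SD (nm) of the per-trimer out-of-plane z offset.
#' @param background_trace_density Nonspecific background traces per square
#'   micrometre (unreported for the real samples; free parameter).
#' @param multi_emitter_fraction Probability that a trace is contaminated
#'   by a second emitter; contaminated traces draw cfr/efo from the
#'   "dirty" distributions.
#' @param cfr_clean,cfr_dirty,efo_clean,efo_dirty Length-2 `c(mean, sd)`
#'   parameters of truncated normal distributions for the per-localization
#'   quality metrics. Clean cfr is truncated below 0.8 and dirty cfr above
#'   0.8, so filter efficacy is measurable against ground truth; efo in
#'   kHz.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return An object of class `synth_minflux_config`.
#' @export
synth_minflux_config <- function(n_trimers = 50, field_size = NULL,
                                 interblade_mean = 21.7, interblade_sd = 5.5,
                                 label_efficiency = 0.8, traces_per_label = 3,
                                 locs_per_trace = 6, loc_sd = 2,
                                 linkage_sd = 1.5, z_plane_sd = 10,
                                 background_trace_density = 2,
                                 multi_emitter_fraction = 0.1,
                                 cfr_clean = c(0.4, 0.15),
                                 cfr_dirty = c(1.1, 0.15),
                                 efo_clean = c(60, 15),
                                 efo_dirty = c(250, 50),
                                 seed = 1L) {
  num <- c(n_trimers = n_trimers, interblade_mean = interblade_mean,
           interblade_sd = interblade_sd,
           label_efficiency = label_efficiency,
           traces_per_label = traces_per_label,
           locs_per_trace = locs_per_trace, loc_sd = loc_sd,
           linkage_sd = linkage_sd, z_plane_sd = z_plane_sd,
           background_trace_density = background_trace_density,
           multi_emitter_fraction = multi_emitter_fraction,
           cfr_clean, cfr_dirty, efo_clean, efo_dirty, seed = seed)
  if (!all(is.finite(num))) {
    stop("non-finite value in synthetic MINFLUX configuration", call. = FALSE)
  }
  if (!is.null(field_size) && (!is.finite(field_size) || field_size <= 0)) {
    stop("field_size must be a positive finite number or NULL", call. = FALSE)
  }
  stopifnot(
    n_trimers >= 0,
    label_efficiency >= 0, label_efficiency <= 1,
    multi_emitter_fraction >= 0, multi_emitter_fraction <= 1,
    interblade_mean > 0, interblade_sd >= 0,
    loc_sd >= 0, linkage_sd >= 0, z_plane_sd >= 0,
    background_trace_density >= 0,
    traces_per_label > 0, locs_per_trace > 0
  )
  structure(
    list(n_trimers = as.integer(n_trimers), field_size = field_size,
         interblade_mean = interblade_mean, interblade_sd = interblade_sd,
         label_efficiency = label_efficiency,
         traces_per_label = traces_per_label,
         locs_per_trace = locs_per_trace, loc_sd = loc_sd,
         linkage_sd = linkage_sd, z_plane_sd = z_plane_sd,
         background_trace_density = background_trace_density,
         multi_emitter_fraction = multi_emitter_fraction,
         cfr_clean = cfr_clean, cfr_dirty = cfr_dirty,
         efo_clean = efo_clean, efo_dirty = efo_dirty,
         seed = as.integer(seed)),
    class = "synth_minflux_config"
  )
}

# normal draws truncated to an interval, by rejection
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out > upper)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower | out > upper)
    tries <- tries + 1
  }
  if (length(bad) > 0) out[bad] <- pmin(pmax(mean, lower + sd * 1e-6), upper)
  out
}

# place n points uniformly in [0, L]^2 with minimum pairwise separation
.place_separated <- function(n, L, min_sep) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < n) {
    cand <- stats::runif(2, 0, L)
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= min_sep) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1
    if (tries > 4000 * max(n, 1)) {
      stop("field too small to place ", n, " trimers ", min_sep,
           " nm apart; enlarge field_size", call. = FALSE)
    }
  }
  pts
}

#' Generate a synthetic MINFLUX localization dataset with ground truth
#'
#' Places `n_trimers` equilateral-up-to-jitter triangles of blade-tip label
#' sites in the field (centroids at least 150 nm apart so the isolation
#' rule is meaningful), draws DNA-PAINT binding traces for every labelled
#' protomer and nonspecific background traces, and emits per-localization
#' noise and quality metrics. Emitted z values are divided by 0.7 so the
#' pipeline's z-scaling correction recovers the true geometry rather than
#' being bypassed. Timestamps are sequential per trace; only their ordering
#' is used downstream.
#'
#' @param config A [synth_minflux_config()].
#' @return A list with
#'   \describe{
#'     \item{localizations}{data frame in the package dialect
#'       (`tid,x_nm,y_nm,z_nm,cfr,efo,t_s`).}
#'     \item{truth}{list with `trimers` (per-trimer centroid, vertex and
#'       label positions, labelled flags, vertex- and label-based true
#'       interblade distances) and `traces` (per-TID origin: trimer and
#'       protomer index, or background; contaminated flag).}
#'   }
#' @export
generate_minflux_dataset <- function(config = synth_minflux_config()) {
  stopifnot(inherits(config, "synth_minflux_config"))
  set.seed(config$seed)
  n <- config$n_trimers
  L <- if (is.null(config$field_size)) {
    max(600, ceiling(sqrt(max(n, 1))) * 250)
  } else {
    config$field_size
  }

  centroids <- .place_separated(n, L, min_sep = 150)
  sides <- .rtruncnorm(n, config$interblade_mean, config$interblade_sd,
                       lower = 0, upper = 40)
  theta0 <- stats::runif(n, 0, 2 * pi)
  z_off <- stats::rnorm(n, 0, config$z_plane_sd)

  trimer_rows <- vector("list", n)
  # trace origins accumulated as flat vectors; localizations expanded at the
  # end from per-trace positions + counts (much faster than per-trace rbind)
  tr_pos <- list(); tr_trimer <- integer(); tr_protomer <- integer()
  tid <- 0L

  emit_trace <- function(pos, origin_trimer, origin_protomer) {
    tid <<- tid + 1L
    tr_pos[[tid]] <<- pos
    tr_trimer[tid] <<- origin_trimer
    tr_protomer[tid] <<- origin_protomer
  }

  for (i in seq_len(n)) {
    r <- sides[i] / sqrt(3)       # circumradius of equilateral triangle
    ang <- theta0[i] + c(0, 2, 4) * pi / 3
    vx <- centroids[i, 1] + r * cos(ang)
    vy <- centroids[i, 2] + r * sin(ang)
    vz <- rep(z_off[i], 3)
    lab_off <- matrix(stats::rnorm(9, 0, config$linkage_sd), ncol = 3)
    lx <- vx + lab_off[, 1]; ly <- vy + lab_off[, 2]; lz <- vz + lab_off[, 3]
    labelled <- stats::runif(3) < config$label_efficiency
    vert <- cbind(vx, vy, vz)
    labp <- cbind(lx, ly, lz)
    trimer_rows[[i]] <- data.frame(
      trimer_id = i, cx = centroids[i, 1], cy = centroids[i, 2], cz = z_off[i],
      vx1 = vx[1], vy1 = vy[1], vz1 = vz[1], vx2 = vx[2], vy2 = vy[2],
      vz2 = vz[2], vx3 = vx[3], vy3 = vy[3], vz3 = vz[3],
      lx1 = lx[1], ly1 = ly[1], lz1 = lz[1], lx2 = lx[2], ly2 = ly[2],
      lz2 = lz[2], lx3 = lx[3], ly3 = ly[3], lz3 = lz[3],
      labelled1 = labelled[1], labelled2 = labelled[2],
      labelled3 = labelled[3],
      true_interblade_nm = mean(stats::dist(vert)),
      label_interblade_nm = mean(stats::dist(labp)))
    for (p in which(labelled)) {
      k <- max(1L, stats::rpois(1, config$traces_per_label))
      for (kk in seq_len(k)) emit_trace(labp[p, ], i, p)
    }
  }

  area_um2 <- (L / 1000)^2
  n_bg <- stats::rpois(1, config$background_trace_density * area_um2)
  for (b in seq_len(n_bg)) {
    pos <- c(stats::runif(1, 0, L), stats::runif(1, 0, L),
             stats::runif(1, -30, 30))
    emit_trace(pos, NA_integer_, NA_integer_)
  }

  n_tr <- tid
  if (n_tr > 0) {
    dirty <- stats::runif(n_tr) < config$multi_emitter_fraction
    m <- pmax(3L, stats::rpois(n_tr, config$locs_per_trace))
    total <- sum(m)
    tid_vec <- rep.int(seq_len(n_tr), m)
    pos_mat <- do.call(rbind, tr_pos)[tid_vec, , drop = FALSE]
    noise <- matrix(stats::rnorm(3 * total, 0, config$loc_sd), ncol = 3)
    dirty_loc <- dirty[tid_vec]
    cfr <- numeric(total); efo <- numeric(total)
    cfr[!dirty_loc] <- .rtruncnorm(sum(!dirty_loc), config$cfr_clean[1],
                                   config$cfr_clean[2], lower = 0,
                                   upper = 0.8 - 1e-9)
    cfr[dirty_loc] <- .rtruncnorm(sum(dirty_loc), config$cfr_dirty[1],
                                  config$cfr_dirty[2], lower = 0.8)
    efo[!dirty_loc] <- .rtruncnorm(sum(!dirty_loc), config$efo_clean[1],
                                   config$efo_clean[2], lower = 0)
    efo[dirty_loc] <- .rtruncnorm(sum(dirty_loc), config$efo_dirty[1],
                                  config$efo_dirty[2], lower = 0)
    within <- sequence(m)
    locs <- data.frame(
      tid = tid_vec,
      x_nm = pos_mat[, 1] + noise[, 1],
      y_nm = pos_mat[, 2] + noise[, 2],
      z_nm = (pos_mat[, 3] + noise[, 3]) / 0.7,  # uncorrected export
      cfr = cfr, efo = efo,
      t_s = tid_vec * 10 + within * 0.01)
    traces <- data.frame(
      tid = seq_len(n_tr),
      origin = ifelse(is.na(tr_trimer), "background", "trimer"),
      trimer = tr_trimer, protomer = tr_protomer, contaminated = dirty)
  } else {
    locs <- data.frame(tid = integer(), x_nm = numeric(), y_nm = numeric(),
                       z_nm = numeric(), cfr = numeric(), efo = numeric(),
                       t_s = numeric())
    traces <- data.frame(tid = integer(), origin = character(),
                         trimer = integer(), protomer = integer(),
                         contaminated = logical())
  }
  truth <- list(
    trimers = if (n > 0) do.call(rbind, trimer_rows) else data.frame(),
    traces = traces
  )
  list(localizations = locs, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the localization table in the pipeline CSV dialect plus
#' ground-truth sidecar CSVs (`*_truth_trimers.csv`, `*_truth_traces.csv`).
#'
#' @param dataset Result of [generate_minflux_dataset()].
#' @param path Path of the localization CSV; sidecars are derived from it.
#' @return `path`, invisibly.
#' @export
write_minflux_dataset <- function(dataset, path) {
  write_localizations(dataset$localizations, path)
  stem <- sub("\\.csv$", "", path)
  utils::write.csv(dataset$truth$trimers, paste0(stem, "_truth_trimers.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth$traces, paste0(stem, "_truth_traces.csv"),
                   row.names = FALSE)
  invisible(path)
}
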