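# Synthetic H&E renderer. Sections are composed in stain-concentration
# space (hematoxylin/eosin OD maps) from simple geometric primitives with a
# known per-pixel label, then rendered to RGB through the same Beer-Lambert
# model the stain module inverts: I = white * 10^(-M c), plus additive
# Gaussian intensity noise. Every random draw flows from the single seed.

#' Specification of a synthetic section
#'
#' Defaults emulate a mid-section of a murine long bone at 1 um/pixel:
#' a cortical ring with a few trabeculae, densely packed nucleated cells,
#' delipidated adipocyte ghosts with thin eosinophilic membranes (one rim
#' nucleus each with probability 0.5), RBC-speckled and serous interstitium,
#' and scattered sub-adipocyte white voids forming the undetected remainder.
#'
#' @param dims Image height and width in pixels.
#' @param pixel_size um per pixel.
#' @param frac_hemato,frac_adipo,frac_interstitium,frac_undetected Target
#'   fractions of the true marrow area (cavity minus bone). They must sum to
#'   at most 1; any shortfall is added to the interstitium.
#' @param cortical_ring Render a cortical bone ring.
#' @param cortical_thickness Ring thickness, um.
#' @param trabecula_count Number of trabecular spicules in the cavity.
#' @param ghost_logmean,ghost_logsd Lognormal parameters of the ghost radius
#'   distribution (um; default median 22 um, i.e. ~1500 um^2 ghosts).
#' @param nucleus_radius Nuclear radius, um.
#' @param nuclei_packing Area fraction of nuclei inside hematopoietic
#'   territory.
#' @param membrane_thickness Ghost membrane thickness, um.
#' @param rim_nucleus_prob Probability that a ghost carries one rim nucleus.
#' @param noise_sd Additive Gaussian intensity noise (0-255 scale).
#' @param white_reference Per-channel background intensity.
#' @param membrane_erase_frac Fraction of membrane wall length whose eosin
#'   is erased (fragmentation stressor; 0 = intact membranes).
#' @param seed Integer seed; fixed seed implies bitwise-reproducible output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(dims = c(384L, 384L), pixel_size = 1,
                           frac_hemato = 0.55, frac_adipo = 0.20,
                           frac_interstitium = 0.17, frac_undetected = 0.03,
                           cortical_ring = TRUE, cortical_thickness = 14,
                           trabecula_count = 3L,
                           ghost_logmean = log(22), ghost_logsd = 0.22,
                           nucleus_radius = 2.5, nuclei_packing = 0.65,
                           membrane_thickness = 1.5, rim_nucleus_prob = 0.5,
                           noise_sd = 3, white_reference = c(242, 240, 244),
                           membrane_erase_frac = 0, seed = 1L) {
  fr <- c(frac_hemato, frac_adipo, frac_interstitium, frac_undetected)
  if (any(fr < 0) || sum(fr) > 1 + 1e-9)
    stop("compartment fractions must be >= 0 and sum to <= 1")
  rm(fr)
  structure(as.list(environment()), class = "synthetic_spec")
}

# ---- geometric primitives (pixel units; x = column, y = row) -------------

.grid <- function(H, W) list(x = matrix(rep(seq_len(W), each = H), H, W) - 0.5,
                             y = matrix(rep(seq_len(H), W), H, W) - 0.5)

.disk <- function(g, cx, cy, r) (g$x - cx)^2 + (g$y - cy)^2 <= r^2

.ellipse <- function(g, cx, cy, a, b, theta) {
  xr <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  yr <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

.circle_polygon <- function(cx, cy, r, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Render stain concentrations to RGB
#'
#' The exact forward model of the stain module: per pixel,
#' `I = white * 10^(-M c)` with `M` the stain OD basis, rounded to 8 bits.
#'
#' @param conc List with H x W matrices `hema` and `eosin` (and optionally
#'   `residual`) of non-negative OD concentrations.
#' @param vectors Stain basis from [stain_vectors()].
#' @param white Per-channel white intensity (length 3).
#' @return H x W x 3 array of 0-255 integers (stored as doubles).
#' @export
forward_stain_render <- function(conc, vectors = stain_vectors(),
                                 white = c(242, 240, 244)) {
  H <- nrow(conc$hema); W <- ncol(conc$hema)
  res <- if (!is.null(conc$residual)) conc$residual else matrix(0, H, W)
  cmat <- cbind(as.vector(conc$hema), as.vector(conc$eosin), as.vector(res))
  od <- cmat %*% t(vectors$M)
  img <- array(0, dim = c(H, W, 3))
  for (c in 1:3) img[, , c] <- matrix(white[c] * 10^(-od[, c]), H, W)
  round(pmin(pmax(img, 0), 255))
}

# stain ODs of the rendered primitives
.OD <- list(bone_e = 0.55, bone_h = 0.03, membrane_e = 0.80,
            nucleus_h = 0.90, nucleus_e = 0.08, hemato_wash_h = 0.30,
            hemato_wash_e = 0.22, serous_e = 0.18, rbc_e = 0.55)

# Place non-overlapping ghost disks inside the allowed region until the
# target pixel count is reached. Dense targets (> 35% fill) start from a
# jittered hexagonal lattice (random sequential placement jams near ~50%
# for equal disks, well below dense marrow adiposity); a random sequential
# top-up pass then fills interstices and boundaries with smaller ghosts,
# capping each radius by the locally available clearance. r_min keeps every
# rendered ghost interior above the default minimum adipocyte size.
.place_ghosts <- function(g, allowed_dist, target_px, r_mu, r_sd, gap,
                          r_min = 9, max_attempts = 1000L,
                          area_fun = function(r) pi * r^2) {
  H <- nrow(allowed_dist); W <- ncol(allowed_dist)
  total_allowed <- sum(allowed_dist > 0)
  cx <- numeric(0); cy <- numeric(0); rr <- numeric(0)
  area <- 0
  if (target_px <= 0 || total_allowed == 0)
    return(list(cx = cx, cy = cy, r = rr))
  frac <- target_px / total_allowed
  local_cap <- function(x, y) {
    yi <- pmin(pmax(round(y + 0.5), 1), H); xj <- pmin(pmax(round(x + 0.5), 1), W)
    cap <- allowed_dist[yi, xj] - gap
    if (length(cx))
      cap <- min(cap, sqrt((cx - x)^2 + (cy - y)^2) - rr - gap)
    cap
  }
  if (frac > 0.35) {
    r_med <- exp(r_mu)
    pitch <- sqrt((2 / sqrt(3)) * pi * r_med^2 / min(0.85, 1.25 * frac))
    pitch <- max(pitch, 2 * r_min + gap)
    rows <- seq(1, H, by = pitch * sqrt(3) / 2)
    pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
      xs <- seq(1 + (i %% 2) * pitch / 2, W, by = pitch)
      cbind(xs, rows[i])
    }))
    pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
    for (i in seq_len(nrow(pts))) {
      if (area >= target_px) break
      x <- pts[i, 1] + stats::runif(1, -1, 1)
      y <- pts[i, 2] + stats::runif(1, -1, 1)
      r <- min(stats::rlnorm(1, r_mu, r_sd), (pitch - gap) / 2, local_cap(x, y))
      if (r < r_min) next
      cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r)
      area <- area + area_fun(r)
    }
  }
  attempts <- 0L
  ok_idx <- which(allowed_dist > r_min + gap)
  while (area < target_px && attempts < max_attempts && length(ok_idx)) {
    attempts <- attempts + 1L
    p <- ok_idx[sample.int(length(ok_idx), 1L)]
    y <- ((p - 1L) %% H) + 0.5; x <- ((p - 1L) %/% H) + 0.5
    r <- min(stats::rlnorm(1, r_mu, r_sd), local_cap(x, y))
    if (r < r_min) next
    cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r)
    area <- area + area_fun(r)
    attempts <- 0L
  }
  if (area < target_px && attempts >= max_attempts)
    stop("infeasible packing: adiposity target unreachable after ",
         max_attempts, " placement attempts")
  list(cx = cx, cy = cy, r = rr)
}

# Confluent ghost pocket for dense adiposity: a disk-shaped pocket of the
# marrow is tiled by nearest-seed (Voronoi) cells from a jittered hexagonal
# seed layout; walls between cells and the pocket rim carry the membrane.
# Cells are selected in random order until the interior target is reached.
.voronoi_ghosts <- function(g, allowed, dist_free, target_px, r_med, memb,
                            cx0, cy0) {
  H <- nrow(allowed); W <- ncol(allowed)
  A_p <- min(target_px / 0.82, 0.95 * sum(allowed))
  R_p <- sqrt(A_p / pi)
  pocket <- .disk(g, cx0, cy0, R_p) & allowed
  guard <- 0L
  while (sum(pocket) < A_p && guard < 12L) {
    guard <- guard + 1L
    R_p <- R_p * 1.12
    pocket <- .disk(g, cx0, cy0, R_p) & allowed
  }
  pitch <- 1.9 * r_med
  rows <- seq(1, H, by = pitch * sqrt(3) / 2)
  seeds <- do.call(rbind, lapply(seq_along(rows), function(i) {
    xs <- seq(1 + (i %% 2) * pitch / 2, W, by = pitch)
    cbind(xs + stats::runif(length(xs), -0.15, 0.15) * pitch,
          rows[i] + stats::runif(length(xs), -0.15, 0.15) * pitch)
  }))
  yi <- pmin(pmax(round(seeds[, 2] + 0.5), 1), H)
  xj <- pmin(pmax(round(seeds[, 1] + 0.5), 1), W)
  seeds <- seeds[pocket[cbind(yi, xj)], , drop = FALSE]
  n <- nrow(seeds)
  empty <- list(interior = allowed & FALSE, membrane = allowed & FALSE,
                ids = matrix(0L, H, W), cx = numeric(0), cy = numeric(0))
  if (n == 0L) return(empty)
  idx <- which(pocket)
  px <- ((idx - 1L) %/% H) + 0.5; py <- ((idx - 1L) %% H) + 0.5
  best_d <- rep(Inf, length(idx)); best_i <- integer(length(idx))
  second_d <- rep(Inf, length(idx))
  for (i in seq_len(n)) {
    d <- sqrt((px - seeds[i, 1])^2 + (py - seeds[i, 2])^2)
    closer <- d < best_d
    second_d[closer] <- best_d[closer]
    upd2 <- !closer & d < second_d
    second_d[upd2] <- d[upd2]
    best_d[closer] <- d[closer]
    best_i[closer] <- i
  }
  pocket_edge <- matrix(as.numeric(EBImage::distmap(pocket * 1)), H, W)
  wall <- (second_d - best_d) < memb | pocket_edge[idx] < memb
  # accumulate cells (random order) until the interior target is met
  ord <- sample.int(n)
  sel <- logical(n)
  cell_int_px <- tabulate(best_i[!wall], nbins = n)
  acc <- 0
  for (i in ord) {
    if (acc >= target_px) break
    if (cell_int_px[i] < 150) next
    sel[i] <- TRUE
    acc <- acc + cell_int_px[i]
  }
  keep <- sel[best_i]
  ids <- matrix(0L, H, W)
  new_id <- cumsum(sel)
  ids[idx[keep & !wall]] <- new_id[best_i[keep & !wall]]
  interior <- ids > 0L
  membrane <- matrix(FALSE, H, W)
  membrane[idx[keep & wall]] <- TRUE
  list(interior = interior, membrane = membrane, ids = ids,
       cx = seeds[sel, 1], cy = seeds[sel, 2])
}

# stamp disks of radius r centered at integer pixel indices `centers`
# (linear indices) into a logical matrix, clipped to `region`
.stamp_disks <- function(dims, centers, r, region = NULL) {
  H <- dims[1]; W <- dims[2]
  out <- matrix(FALSE, H, W)
  if (!length(centers)) return(out)
  ri <- ceiling(r)
  off <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
  cy <- ((centers - 1L) %% H) + 1L
  cx <- ((centers - 1L) %/% H) + 1L
  for (k in seq_len(nrow(off))) {
    yy <- cy + off$dy[k]; xx <- cx + off$dx[k]
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    out[cbind(yy[ok], xx[ok])] <- TRUE
  }
  if (!is.null(region)) out <- out & region
  out
}

# scatter disks of radius r over `region` until `target_px` covered
.scatter_disks <- function(g, region, target_px, r) {
  out <- region & FALSE
  idx <- which(region)
  if (!length(idx) || target_px <= 0) return(out)
  H <- nrow(region)
  n_per_batch <- max(8L, ceiling(target_px / (pi * r^2) / 3))
  guard <- 0L
  while (sum(out) < target_px && guard < 60L) {
    guard <- guard + 1L
    p <- idx[sample.int(length(idx), min(n_per_batch, length(idx)))]
    out <- out | .stamp_disks(dim(region), p, r, region)
  }
  out
}

#' Generate a synthetic bone-marrow section with ground truth
#'
#' Builds the geometry (cortical ring, trabeculae, ghosts, nuclei,
#' interstitium, voids), renders it to RGB through the Beer-Lambert forward
#' model with additive Gaussian noise, and returns the image together with
#' per-pixel truth labels, a per-ghost truth table, and a matching
#' annotation set (tissue polygon just inside the cortical outline, one
#' 10 x 10 background window over an empty region inside the ROI).
#'
#' Realized compartment fractions are enforced within +-3 percentage points
#' of the targets by rejection resampling (up to five attempts on derived
#' seeds).
#'
#' @param spec A `synthetic_spec`.
#' @param seed Optional seed overriding `spec$seed`.
#' @return List with `image` (a `calibrated_image`), `truth` (list:
#'   `labels` matrix over `MQ_LABELS` codes, `ghosts` truth table,
#'   `fractions` realized fractions of the true marrow area) and
#'   `annotations` (an `annotation_set`).
#' @export
generate_marrow_section <- function(spec, seed = NULL) {
  if (!is.null(seed)) spec$seed <- seed
  targets <- c(hemato = spec$frac_hemato, adipo = spec$frac_adipo,
               interstitium = spec$frac_interstitium,
               undetected = spec$frac_undetected)
  last_err <- NULL
  for (attempt in 0:4) {
    out <- tryCatch(.render_marrow_once(spec, spec$seed + 7919L * attempt),
                    error = function(e) e)
    if (inherits(out, "error")) { last_err <- out; next }
    realized <- out$truth$fractions[names(targets)]
    # the interstitium absorbs whatever the others do not claim; only the
    # directly placed compartments are held to the tolerance
    dev <- abs(realized - targets)[c("hemato", "adipo", "undetected")]
    if (all(dev <= 0.03)) return(out)
    last_err <- simpleError(sprintf(
      "realized fractions off target by %.1f points", 100 * max(dev)))
  }
  stop("could not realize target fractions within 3 points: ",
       conditionMessage(last_err))
}

.render_marrow_once <- function(spec, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ps <- spec$pixel_size
  H <- spec$dims[1]; W <- spec$dims[2]
  g <- .grid(H, W)
  cx0 <- W / 2; cy0 <- H / 2
  r_outer <- min(H, W) / 2 - 4
  t_cort <- if (spec$cortical_ring) spec$cortical_thickness / ps else 0
  r_cavity <- r_outer - t_cort
  outer_disk <- .disk(g, cx0, cy0, r_outer)
  cavity <- .disk(g, cx0, cy0, r_cavity)
  bone <- outer_disk & !cavity
  # trabecular spicules
  if (spec$trabecula_count > 0) {
    for (k in seq_len(spec$trabecula_count)) {
      th <- stats::runif(1, 0, pi)
      rad <- stats::runif(1, 0.35, 0.75) * r_cavity
      ang <- stats::runif(1, 0, 2 * pi)
      tc <- c(cx0 + rad * cos(ang), cy0 + rad * sin(ang))
      bone <- bone | (.ellipse(g, tc[1], tc[2],
                               stats::runif(1, 30, 45) / ps,
                               stats::runif(1, 7, 10) / ps, th) & cavity)
    }
  }
  ma_truth <- cavity & !bone
  ma_px <- sum(ma_truth)

  # ---- adipocyte ghosts --------------------------------------------------
  memb <- spec$membrane_thickness / ps
  r_nuc <- spec$nucleus_radius / ps
  allowed <- ma_truth & !mask_dilate(bone, 2L)
  dist_free <- matrix(as.numeric(EBImage::distmap(allowed * 1)), H, W)
  target_adipo <- spec$frac_adipo * ma_px
  ghost_interior <- matrix(FALSE, H, W)
  membrane <- matrix(FALSE, H, W)
  rim_nuclei <- matrix(FALSE, H, W)
  ghost_ids <- matrix(0L, H, W)
  gh <- list(cx = numeric(0), cy = numeric(0))
  if (target_adipo / max(ma_px, 1) > 0.38) {
    # dense adiposity: a confluent yellow-marrow pocket of ghosts sharing
    # membrane walls (isolated disks cannot pack this tightly)
    pk <- .voronoi_ghosts(g, allowed, dist_free, target_adipo,
                          exp(spec$ghost_logmean - log(ps)), memb,
                          cx0, cy0)
    ghost_interior <- pk$interior; membrane <- pk$membrane
    ghost_ids <- pk$ids; gh <- list(cx = pk$cx, cy = pk$cy)
  } else if (target_adipo > 0) {
    # rim-nucleus and membrane losses relative to the placed disk footprint
    eff <- function(r) pi * (r - memb)^2
    gh <- .place_ghosts(g, dist_free, target_adipo /
                          (1 - spec$rim_nucleus_prob * 0.01),
                        spec$ghost_logmean - log(ps), spec$ghost_logsd,
                        gap = memb + 2, area_fun = eff)
    for (i in seq_along(gh$cx)) {
      d2 <- (g$x - gh$cx[i])^2 + (g$y - gh$cy[i])^2
      interior <- d2 <= (gh$r[i] - memb)^2
      membrane <- membrane | (d2 <= gh$r[i]^2 & !interior)
      ghost_interior <- ghost_interior | interior
      ghost_ids[interior] <- i
    }
  }
  n_ghost <- length(gh$cx)
  # one rim nucleus per ghost with the configured probability
  for (i in seq_len(n_ghost)) {
    if (stats::runif(1) >= spec$rim_nucleus_prob) next
    sel <- which(ghost_ids == i)
    if (length(sel) < 4 * pi * r_nuc^2) next
    yy <- ((sel - 1L) %% H) + 0.5; xx <- ((sel - 1L) %/% H) + 0.5
    d_edge <- sqrt((xx - gh$cx[i])^2 + (yy - gh$cy[i])^2)
    k <- which.max(d_edge)  # near the rim
    nuc <- .disk(g, xx[k], yy[k], r_nuc)
    nuc <- nuc & ghost_ids == i
    rim_nuclei <- rim_nuclei | nuc
    ghost_interior <- ghost_interior & !nuc
    ghost_ids[nuc] <- 0L
  }
  ghost_zone <- ghost_interior | membrane | rim_nuclei

  # ---- hematopoietic territory ------------------------------------------
  target_h <- spec$frac_hemato * ma_px
  avoid <- mask_dilate(ghost_zone, 2L) | bone
  hemato_region <- matrix(FALSE, H, W)
  free <- ma_truth & !avoid
  blob_r <- 16 / ps
  guard <- 0L
  idx_free <- which(free)
  while (sum(hemato_region) < target_h && guard < 4000L && length(idx_free)) {
    guard <- guard + 1L
    p <- idx_free[sample.int(length(idx_free), 1L)]
    y <- ((p - 1L) %% H) + 0.5; x <- ((p - 1L) %/% H) + 0.5
    hemato_region <- hemato_region |
      (.disk(g, x, y, stats::runif(1, 0.7, 1.3) * blob_r) & free)
  }
  if (sum(hemato_region) < target_h - 0.02 * ma_px && target_h > 0)
    stop("infeasible packing: hematopoietic target unreachable")

  # nuclei inside the territory
  nuclei <- matrix(FALSE, H, W)
  n_nuc <- round(spec$nuclei_packing * sum(hemato_region) / (pi * r_nuc^2))
  if (n_nuc > 0) {
    idx_h <- which(hemato_region)
    p <- idx_h[sample.int(length(idx_h), min(n_nuc, length(idx_h)),
                          replace = TRUE)]
    nuclei <- .stamp_disks(c(H, W), p, r_nuc, hemato_region)
  }

  # ---- interstitium, voids, background window ---------------------------
  interstitium <- ma_truth & !ghost_zone & !hemato_region & !membrane
  inter_dist <- matrix(as.numeric(EBImage::distmap(interstitium * 1)), H, W)
  # background window: 10x10 empty patch inside the ROI
  bg_ok <- which(inter_dist > 9)
  if (!length(bg_ok)) stop("infeasible packing: no room for background window")
  p <- bg_ok[sample.int(length(bg_ok), 1L)]
  by <- ((p - 1L) %% H) + 1L; bx <- ((p - 1L) %/% H) + 1L
  bg_rect <- matrix(FALSE, H, W)
  bg_rect[(by - 5L):(by + 4L), (bx - 5L):(bx + 4L)] <- TRUE
  # white voids (sub-adipocyte size -> undetected)
  target_u <- spec$frac_undetected * ma_px
  voids <- bg_rect
  vc <- list(x = bx - 0.5, y = by - 0.5, r = 8)
  guard <- 0L
  while (sum(voids) < target_u && guard < 3000L) {
    guard <- guard + 1L
    r <- stats::runif(1, 3, 5) / ps
    ok <- which(inter_dist > r + 2)
    if (!length(ok)) break
    p <- ok[sample.int(length(ok), 1L)]
    y <- ((p - 1L) %% H) + 0.5; x <- ((p - 1L) %/% H) + 0.5
    if (any((vc$x - x)^2 + (vc$y - y)^2 < (vc$r + r + 3)^2)) next
    voids <- voids | .disk(g, x, y, r)
    vc$x <- c(vc$x, x); vc$y <- c(vc$y, y); vc$r <- c(vc$r, r)
  }
  interstitium_final <- interstitium & !voids
  # RBC speckle over part of the interstitium
  rbc <- .scatter_disks(g, interstitium_final, 0.35 * sum(interstitium_final),
                        3 / ps)

  # ---- stain maps and render --------------------------------------------
  hema <- matrix(0, H, W); eosin <- matrix(0, H, W)
  eosin[interstitium_final] <- .OD$serous_e
  eosin[rbc] <- .OD$rbc_e
  hema[hemato_region] <- .OD$hemato_wash_h
  eosin[hemato_region] <- .OD$hemato_wash_e
  hema[nuclei | rim_nuclei] <- .OD$nucleus_h
  eosin[nuclei | rim_nuclei] <- .OD$nucleus_e
  eosin[membrane] <- .OD$membrane_e
  eosin[bone] <- .OD$bone_e
  hema[bone] <- .OD$bone_h
  eosin[ghost_interior | voids] <- 0
  hema[ghost_interior | voids] <- 0

  img <- forward_stain_render(list(hema = hema, eosin = eosin),
                              white = spec$white_reference)
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
  }

  # ---- annotations and truth --------------------------------------------
  r_tissue <- if (spec$cortical_ring) r_outer - 2 else r_cavity
  tissue_poly <- .circle_polygon(cx0, cy0, r_tissue)
  bg_poly <- cbind(c(bx - 6, bx + 4, bx + 4, bx - 6),
                   c(by - 6, by - 6, by + 4, by + 4))
  annotations <- structure(list(
    list(class = "Tissue", rings = list(tissue_poly)),
    list(class = "Background", rings = list(bg_poly))
  ), class = "annotation_set")
  analysis <- polygon_mask(tissue_poly, c(H, W))

  labels <- matrix(MQ_LABELS[["EXCLUDED"]], H, W)
  labels[analysis & ma_truth] <- MQ_LABELS[["UNDETECTED"]]
  labels[analysis & (interstitium_final | membrane)] <- MQ_LABELS[["INTERSTITIUM"]]
  labels[analysis & ghost_interior] <- MQ_LABELS[["ADIPO"]]
  labels[analysis & (hemato_region | rim_nuclei)] <- MQ_LABELS[["HEMATO"]]
  labels[analysis & voids] <- MQ_LABELS[["UNDETECTED"]]
  labels[analysis & bone] <- MQ_LABELS[["BONE"]]

  ma_in <- sum(labels != MQ_LABELS[["EXCLUDED"]] & labels != MQ_LABELS[["BONE"]])
  frac <- c(
    hemato = sum(labels == MQ_LABELS[["HEMATO"]]) / ma_in,
    adipo = sum(labels == MQ_LABELS[["ADIPO"]]) / ma_in,
    interstitium = sum(labels == MQ_LABELS[["INTERSTITIUM"]]) / ma_in,
    undetected = sum(labels == MQ_LABELS[["UNDETECTED"]]) / ma_in)

  ghost_tab <- if (n_ghost) {
    do.call(rbind, lapply(seq_len(n_ghost), function(i) {
      npx <- sum(ghost_ids == i & analysis)
      data.frame(id = i, n_px = npx, area_um2 = npx * ps^2,
                 centroid_x = gh$cx[i], centroid_y = gh$cy[i])
    }))
  } else data.frame(id = integer(), n_px = integer(), area_um2 = numeric(),
                    centroid_x = numeric(), centroid_y = numeric())
  ghost_tab <- ghost_tab[ghost_tab$n_px > 0, , drop = FALSE]

  image <- structure(list(pixels = img, pixel_size = ps,
                          source_path = sprintf("synthetic-marrow-seed%d", seed)),
                     class = "calibrated_image")
  list(image = image,
       truth = list(labels = labels, ghosts = ghost_tab, fractions = frac,
                    masks = list(bone = bone & analysis,
                                 hemato = (hemato_region | rim_nuclei) & analysis,
                                 adipo = ghost_interior & analysis,
                                 interstitium = (interstitium_final | membrane) & analysis,
                                 analysis = analysis)),
       annotations = annotations)
}

#' Generate a synthetic extramedullary adipose sheet
#'
#' A Voronoi-like tiling of adjacent adipocyte ghosts sharing membrane
#' walls, with sparse stromal nuclei at wall junctions and a serous stromal
#' background between cells; no bone. Setting `membrane_erase_frac > 0`
#' removes the eosin membrane along that fraction of each wall (leaving a
#' void), which stresses the fragmentation step (hypo-fragmentation).
#'
#' @param spec A `synthetic_spec`; relevant fields are `dims`, `pixel_size`,
#'   `ghost_logmean`, `ghost_logsd`, `membrane_thickness`,
#'   `membrane_erase_frac`, `noise_sd`, `white_reference` and `seed`.
#' @param n_ghosts Number of ghost cells to seed.
#' @param seed Optional override of `spec$seed`.
#' @return List with `image` (a `calibrated_image`) and `truth` (`labels`,
#'   per-ghost `ghosts` table, `cell_ids` matrix of per-pixel truth ghost
#'   ids).
#' @export
generate_adipose_sheet <- function(spec, n_ghosts = 200L, seed = NULL) {
  if (!is.null(seed)) spec$seed <- seed
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  ps <- spec$pixel_size
  H <- spec$dims[1]; W <- spec$dims[2]
  g <- .grid(H, W)
  radii <- stats::rlnorm(n_ghosts, spec$ghost_logmean - log(ps),
                         spec$ghost_logsd)
  margin <- max(radii) + 6
  # seed points: dart throwing with a minimum spacing tied to the radii
  cx <- numeric(0); cy <- numeric(0); rr <- numeric(0)
  attempts <- 0L
  while (length(cx) < n_ghosts && attempts < 40000L) {
    attempts <- attempts + 1L
    x <- stats::runif(1, margin, W - margin)
    y <- stats::runif(1, margin, H - margin)
    r <- radii[length(cx) + 1L]
    if (length(cx) && any(sqrt((cx - x)^2 + (cy - y)^2) < 0.7 * (rr + r))) next
    cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r)
  }
  if (length(cx) < n_ghosts)
    stop("infeasible packing: could not seed ", n_ghosts, " ghost cells")
  # nearest-seed assignment within each seed's radius
  best_d <- matrix(Inf, H, W); best_i <- matrix(0L, H, W)
  second_d <- matrix(Inf, H, W)
  for (i in seq_len(n_ghosts)) {
    d <- sqrt((g$x - cx[i])^2 + (g$y - cy[i])^2)
    closer <- d < best_d
    second_d[closer] <- best_d[closer]
    upd2 <- !closer & d < second_d
    second_d[upd2] <- d[upd2]
    best_d[closer] <- d[closer]
    best_i[closer] <- i
  }
  cells <- best_d <= rr[best_i] & best_i > 0L
  cell_ids <- ifelse(cells, best_i, 0L)
  memb <- spec$membrane_thickness / ps
  # walls: cell pixels near a neighbouring claim or near the cell's rim
  boundary <- cells & ((second_d - best_d) < memb | (rr[best_i] - best_d) < memb)
  interior <- cells & !boundary
  membrane <- boundary
  if (spec$membrane_erase_frac > 0 && any(membrane)) {
    # erase stain on an angular sector of each cell's shared walls (not the
    # outer rim): the hypo-fragmentation failure mode is adjacent ghosts
    # merging through a lost membrane
    shared_wall <- membrane & (second_d - best_d) < memb
    erase <- matrix(FALSE, H, W)
    wedge <- spec$membrane_erase_frac * 2 * pi
    for (i in seq_len(n_ghosts)) {
      idx <- which(shared_wall & best_i == i)
      if (!length(idx)) next
      yy <- ((idx - 1L) %% H) + 0.5; xx <- ((idx - 1L) %/% H) + 0.5
      ang <- (atan2(yy - cy[i], xx - cx[i]) - stats::runif(1, 0, 2 * pi)) %% (2 * pi)
      erase[idx[ang < wedge]] <- TRUE
    }
    membrane <- membrane & !erase
  }
  # stromal nuclei at wall junctions
  r_nuc <- spec$nucleus_radius / ps
  junctions <- which(membrane)
  nuclei <- matrix(FALSE, H, W)
  if (length(junctions)) {
    p <- junctions[sample.int(length(junctions), min(60L, length(junctions)))]
    ys <- ((p - 1L) %% H) + 0.5; xs <- ((p - 1L) %/% H) + 0.5
    for (i in seq_along(p)) nuclei <- nuclei | .disk(g, xs[i], ys[i], r_nuc)
    nuclei <- nuclei & !interior
  }
  stroma <- !cells
  hema <- matrix(0, H, W); eosin <- matrix(0, H, W)
  eosin[stroma] <- .OD$serous_e
  eosin[membrane] <- .OD$membrane_e
  hema[nuclei] <- .OD$nucleus_h
  img <- forward_stain_render(list(hema = hema, eosin = eosin),
                              white = spec$white_reference)
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    img <- round(pmin(pmax(img, 0), 255))
  }
  truth_ids <- ifelse(interior, best_i, 0L)
  ghost_tab <- do.call(rbind, lapply(seq_len(n_ghosts), function(i) {
    npx <- sum(truth_ids == i)
    data.frame(id = i, n_px = npx, area_um2 = npx * ps^2,
               centroid_x = cx[i], centroid_y = cy[i])
  }))
  labels <- matrix(MQ_LABELS[["UNDETECTED"]], H, W)
  labels[stroma | membrane] <- MQ_LABELS[["INTERSTITIUM"]]
  labels[nuclei] <- MQ_LABELS[["HEMATO"]]
  labels[truth_ids > 0L] <- MQ_LABELS[["ADIPO"]]
  image <- structure(list(pixels = img, pixel_size = ps,
                          source_path = sprintf("synthetic-sheet-seed%d", spec$seed)),
                     class = "calibrated_image")
  list(image = image,
       truth = list(labels = labels, ghosts = ghost_tab, cell_ids = truth_ids))
}

#' Write a synthetic fixture to disk
#'
#' Renders a marrow section or adipose sheet and writes the image TIFF, the
#' truth label TIFF, the truth ghost CSV and (for marrow) the annotation
#' GeoJSON into a directory.
#'
#' @param preset `"marrow"` or `"adipo"`.
#' @param out_dir Output directory (created if missing).
#' @param spec Optional `synthetic_spec`; defaults per preset.
#' @param seed Seed override.
#' @return Invisibly, the list of files written.
#' @export
write_synthetic_fixture <- function(preset = c("marrow", "adipo"), out_dir,
                                    spec = NULL, seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- synthetic_spec(seed = seed)
  stem <- file.path(out_dir, paste0("synthetic_", preset))
  if (preset == "marrow") {
    sec <- generate_marrow_section(spec, seed = seed)
    write_image(sec$image, paste0(stem, ".tif"))
    write_label_tiff(sec$truth$labels, paste0(stem, "_truth.tif"))
    utils::write.csv(sec$truth$ghosts, paste0(stem, "_truth_ghosts.csv"),
                     row.names = FALSE)
    .write_annotations_geojson(sec$annotations, paste0(stem, ".geojson"))
    files <- paste0(stem, c(".tif", "_truth.tif", "_truth_ghosts.csv", ".geojson"))
  } else {
    sh <- generate_adipose_sheet(spec, seed = seed)
    write_image(sh$image, paste0(stem, ".tif"))
    write_label_tiff(sh$truth$labels, paste0(stem, "_truth.tif"))
    utils::write.csv(sh$truth$ghosts, paste0(stem, "_truth_ghosts.csv"),
                     row.names = FALSE)
    files <- paste0(stem, c(".tif", "_truth.tif", "_truth_ghosts.csv"))
  }
  invisible(files)
}

# minimal GeoJSON writer for annotation sets (QuPath-compatible classes)
.write_annotations_geojson <- function(annotations, path) {
  cls_name <- c(Tissue = "Tissue Boundaries", Artifact = "Artifacts",
                Background = "Background")
  feats <- lapply(annotations, function(p) {
    coords <- lapply(p$rings, function(ring) {
      ring <- rbind(ring, ring[1, ])  # close the ring
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(classification = list(name = cls_name[[p$class]])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}
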