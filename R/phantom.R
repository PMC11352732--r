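#' Parametric map objects
#'
#' A `parametric_map` holds a pair of 2D quantitative maps — proton-density
#' weighted amplitude `m0` (arbitrary units) and transverse relaxation time
#' `t2star` (ms) — together with a logical tissue `mask` and an integer
#' `subject_id` grouping key used for subject-disjoint train/validation splits.
#' Outside the mask both channels are exactly 0; inside, `t2star` lies in
#' (0, 500] ms.
#'
#' @param m0,t2star numeric matrices of identical dimensions.
#' @param mask logical matrix of the same dimensions.
#' @param subject_id non-negative integer grouping key.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(m0, t2star, mask, subject_id = 0L) {
  check_that(is.matrix(m0) && is.matrix(t2star) && is.matrix(mask),
             "m0, t2star and mask must be matrices")
  check_that(all(dim(m0) == dim(t2star)) && all(dim(m0) == dim(mask)),
             "m0, t2star and mask must share dimensions")
  check_that(is_count(subject_id, min = 0L), "subject_id must be >= 0")
  mask <- mask & TRUE # coerce
  check_that(all(m0 >= 0), "m0 must be non-negative")
  check_that(all(t2star[mask] > 0) && all(t2star[mask] <= 500),
             "t2star inside the mask must lie in (0, 500] ms")
  check_that(all(t2star[!mask] == 0) && all(m0[!mask] == 0),
             "background (outside mask) must be exactly 0")
  structure(list(m0 = m0, t2star = t2star, mask = mask,
                 subject_id = as.integer(subject_id),
                 pixel_grid = dim(m0)),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %d x %d, subject %d, %d tissue px, T2* %.1f-%.1f ms\n",
              nrow(x$m0), ncol(x$m0), x$subject_id, sum(x$mask),
              min(x$t2star[x$mask]), max(x$t2star[x$mask])))
  invisible(x)
}

# Smooth standardized Gaussian random field on an r x c grid.
smooth_field <- function(r, c, sigma = 3) {
  f <- matrix(rnorm(r * c), r, c)
  Sr <- gaussian_smoothing_matrix(r, sigma)
  Sc <- gaussian_smoothing_matrix(c, sigma)
  f <- Sr %*% f %*% t(Sc)
  (f - mean(f)) / max(sd(f), 1e-12)
}

#' Generate a brain-like 2D parametric template
#'
#' Procedurally draws an elliptical head outline containing nested tissue
#' classes with distinct T2* ranges — a CSF-like rim and ventricles
#' (150–250 ms, clipped to 200 ms), a GM-like band (60–80 ms), a WM-like core
#' (45–60 ms) and small vessel-like blobs (15–35 ms) — plus smooth
#' within-class spatial variation. T2* class ranges follow standard 3T
#' literature values. Deterministic given `subject_seed`.
#'
#' @param rows,cols matrix size, each at least 16.
#' @param subject_seed integer seed controlling geometry and tissue layout.
#' @param subject_id grouping key stored in the result (defaults to 0).
#' @return A [parametric_map()].
#' @export
generate_template <- function(rows, cols, subject_seed, subject_id = 0L) {
  check_that(is_count(rows, 16L) && is_count(cols, 16L),
             "rows and cols must be integers >= 16")
  withr::with_seed(as.integer(subject_seed), {
    cx <- cols / 2 * (1 + runif(1, -0.03, 0.03))
    cy <- rows / 2 * (1 + runif(1, -0.03, 0.03))
    rx <- 0.42 * cols * runif(1, 0.95, 1.05)
    ry <- 0.45 * rows * runif(1, 0.95, 1.05)
    th <- runif(1, -pi / 12, pi / 12)
    xg <- matrix(rep(seq_len(cols), each = rows), rows, cols) - cx
    yg <- matrix(rep(seq_len(rows), cols), rows, cols) - cy
    xr <- cos(th) * xg + sin(th) * yg
    yr <- -sin(th) * xg + cos(th) * yg
    rho <- sqrt((xr / rx)^2 + (yr / ry)^2)
    mask <- rho <= 1

    r_gm <- runif(1, 0.90, 0.94) # GM/CSF-rim boundary
    r_wm <- runif(1, 0.52, 0.60) # WM/GM boundary
    cls <- matrix(0L, rows, cols) # 0 bg, 1 wm, 2 gm, 3 csf, 4 vessel
    cls[mask] <- 2L
    cls[mask & rho > r_gm] <- 3L
    cls[mask & rho <= r_wm] <- 1L

    # paired ventricles near the centre -> CSF
    for (sgn in c(-1, 1)) {
      vx <- cx + sgn * 0.14 * cols * runif(1, 0.8, 1.2)
      vy <- cy + 0.02 * rows * runif(1, -1, 1)
      vrx <- 0.06 * cols * runif(1, 0.8, 1.4)
      vry <- 0.12 * rows * runif(1, 0.8, 1.4)
      vent <- ((xg + cx - vx) / vrx)^2 + ((yg + cy - vy) / vry)^2 <= 1
      cls[vent & mask] <- 3L
    }

    # vessel-like low-T2* blobs
    n_ves <- sample(3:6, 1)
    for (i in seq_len(n_ves)) {
      repeat {
        px <- runif(1, 1, cols); py <- runif(1, 1, rows)
        if (sqrt(((px - cx) / rx)^2 + ((py - cy) / ry)^2) < 0.85) break
      }
      vr <- runif(1, 1, 2.5)
      blob <- (xg + cx - px)^2 + (yg + cy - py)^2 <= vr^2
      cls[blob & mask] <- 4L
    }

    f_t2 <- smooth_field(rows, cols, sigma = 3)
    f_m0 <- smooth_field(rows, cols, sigma = 4)

    t2 <- matrix(0, rows, cols)
    wm <- cls == 1L; gm <- cls == 2L; csf <- cls == 3L; ves <- cls == 4L
    t2[wm]  <- pmin(pmax(runif(1, 49, 56) + 4 * f_t2[wm], 45), 60)
    t2[gm]  <- pmin(pmax(runif(1, 66, 74) + 5 * f_t2[gm], 60), 80)
    t2[csf] <- pmin(pmin(pmax(runif(1, 180, 220) + 25 * f_t2[csf], 150), 250), 200)
    t2[ves] <- pmin(pmax(runif(1, 22, 28) + 4 * f_t2[ves], 15), 35)

    m0 <- matrix(0, rows, cols)
    base <- c(0.70, 0.85, 1.00, 0.55) # wm, gm, csf, vessel
    for (k in 1:4) {
      sel <- cls == k
      m0[sel] <- 100 * base[k] * pmax(1 + 0.05 * f_m0[sel], 0.5)
    }
    parametric_map(m0, t2, mask, subject_id = subject_id)
  })
}

rot90_mat <- function(m, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# Nearest-neighbour rotation about the image centre; outside samples -> 0.
rotate_nn <- function(m, angle_deg) {
  if (angle_deg == 0) return(m)
  r <- nrow(m); c <- ncol(m)
  a <- angle_deg * pi / 180
  cy <- (r + 1) / 2; cx <- (c + 1) / 2
  yg <- matrix(rep(seq_len(r), c), r, c) - cy
  xg <- matrix(rep(seq_len(c), each = r), r, c) - cx
  sy <- round(cos(a) * yg - sin(a) * xg + cy)
  sx <- round(sin(a) * yg + cos(a) * xg + cx)
  ok <- sy >= 1 & sy <= r & sx >= 1 & sx <= c
  out <- matrix(0, r, c)
  out[ok] <- m[cbind(sy[ok], sx[ok])]
  out
}

#' Apply a deterministic rigid augmentation to a parametric map
#'
#' Rotates by `k90` quarter turns, optionally flips horizontally/vertically,
#' then applies an optional small-angle rotation with nearest-neighbour
#' resampling (so no non-physical interpolated T2* values are created at
#' tissue borders). `m0`, `t2star` and `mask` are transformed jointly.
#'
#' @param map a [parametric_map()].
#' @param k90 number of 90-degree counter-clockwise rotations (0–3).
#' @param flip_h,flip_v logical; flip along columns / rows.
#' @param angle_deg small rotation angle in degrees (nearest-neighbour).
#' @return A [parametric_map()].
#' @export
apply_rigid_augmentation <- function(map, k90 = 0L, flip_h = FALSE,
                                     flip_v = FALSE, angle_deg = 0) {
  check_that(inherits(map, "parametric_map"), "map must be a parametric_map")
  tf <- function(m) {
    m <- rot90_mat(m, k90)
    if (flip_h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (flip_v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    rotate_nn(m, angle_deg)
  }
  parametric_map(tf(map$m0), tf(map$t2star), tf(map$mask) > 0.5,
                 subject_id = map$subject_id)
}

#' Randomly rotate and flip a parametric map
#'
#' Samples an independent augmentation — a multiple of 90 degrees, horizontal
#' and vertical flips, and (with probability 1/2) a small-angle rotation in
#' \[-10, 10\] degrees resampled nearest-neighbour — and applies it jointly to
#' all channels. Deterministic given `seed`.
#'
#' @param map a [parametric_map()].
#' @param seed integer seed.
#' @return A [parametric_map()] with the same `subject_id`.
#' @export
augment <- function(map, seed) {
  withr::with_seed(as.integer(seed), {
    k90 <- sample(0:3, 1)
    flips <- runif(2) < 0.5
    ang <- if (runif(1) < 0.5) runif(1, -10, 10) else 0
    apply_rigid_augmentation(map, k90, flips[1], flips[2], ang)
  })
}

#' Build a bank of parametric templates across synthetic subjects
#'
#' Each subject gets an independent top-level seed controlling head geometry
#' and tissue layout; the remaining `per_subject - 1` maps per subject are
#' random rotations/flips of that subject's base template and share its
#' `subject_id`, so train/validation splits can be made subject-disjoint.
#'
#' @param n_subjects number of synthetic subjects (>= 2 so a split is possible).
#' @param per_subject maps per subject.
#' @param rows,cols template size.
#' @param seed integer master seed.
#' @return A list of [parametric_map()] with `subject_id` in `0:(n_subjects-1)`.
#' @export
make_template_bank <- function(n_subjects, per_subject, rows = 64L, cols = 64L,
                               seed = 1L) {
  check_that(is_count(n_subjects, 2L), "n_subjects must be >= 2")
  check_that(is_count(per_subject, 1L), "per_subject must be >= 1")
  sseeds <- derive_seeds(seed, n_subjects)
  bank <- vector("list", n_subjects * per_subject)
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    base <- generate_template(rows, cols, sseeds[s], subject_id = s - 1L)
    aseeds <- derive_seeds(sseeds[s], max(per_subject - 1L, 1L))
    for (j in seq_len(per_subject)) {
      idx <- idx + 1L
      bank[[idx]] <- if (j == 1L) base else augment(base, aseeds[j - 1L])
    }
  }
  bank
}

#' Split a template bank subject-disjointly
#'
#' Whole subjects are assigned to the validation partition so that no
#' `subject_id` appears on both sides.
#'
#' @param bank list of [parametric_map()].
#' @param train_fraction fraction of subjects assigned to training
#'   (default 5/6, i.e. a 5:1 split).
#' @return `list(train =, val =)` of parametric maps.
#' @export
split_bank <- function(bank, train_fraction = 5 / 6) {
  ids <- vapply(bank, function(m) m$subject_id, integer(1))
  subj <- sort(unique(ids))
  check_that(length(subj) >= 2L, "bank must span at least 2 subjects")
  n_val <- max(1L, round(length(subj) * (1 - train_fraction)))
  n_val <- min(n_val, length(subj) - 1L)
  val_subj <- utils::tail(subj, n_val)
  list(train = bank[!(ids %in% val_subj)], val = bank[ids %in% val_subj])
}
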