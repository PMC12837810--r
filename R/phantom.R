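# Synthetic retinal phantoms: a seeded clinical cohort with a CMT-derived
# responder rule, layered-retina OCT B-scans carrying three lesion classes
# (ERM line, IRC blobs, SRF pocket), and paired ultra-widefield fundus images.
# These stand in for private clinical acquisitions so every downstream stage is
# testable; the knobs (contrast, area, blur) deliberately span the factors the
# curriculum scorer uses.

#' Default cohort marginals
#'
#' Per-group means/SDs for age, central macular thickness (CMT, micrometers),
#' intraocular pressure (IOP, mmHg) and decimal visual acuity (BCVA), gender
#' counts, and the relative CMT-change distribution that drives the responder
#' rule (responder = CMT decrease of at least 10\% at 3 months). Defaults match
#' a 371-patient / 402-eye referral cohort with 147 responsive and 224
#' non-responsive patients.
#'
#' @return A list with one entry per response group plus the responder
#'   threshold.
#' @export
default_marginals <- function() {
  list(
    threshold = 0.10,
    groups = list(
      responsive = list(
        n = 147L, female = 73L, male = 74L,
        age = c(62.10, 12.86), cmt = c(530.76, 230.57),
        iop = c(16.20, 1.93), bcva = c(0.19, 0.18),
        erm_rate = 43 / 147,
        dcmt = c(0.35, 0.15)     # relative CMT decrease, truncated >= 0.10
      ),
      nonresponsive = list(
        n = 224L, female = 80L, male = 144L,
        age = c(64.53, 11.33), cmt = c(361.33, 184.76),
        iop = c(16.27, 2.04), bcva = c(0.26, 0.20),
        erm_rate = 49 / 224,
        dcmt = c(0.02, 0.07)     # truncated < 0.10 (may be negative)
      )
    )
  )
}

#' Generate a synthetic clinical cohort
#'
#' Draws per-eye records (age, gender, ERM flag, baseline and 3-month CMT, IOP,
#' BCVA). The responder label is always *derived* from the generated CMT pair
#' via [responder_label()], never sampled, so the labelling rule is exercised
#' end to end. When `n_patients` equals the configured group total, group sizes
#' and gender counts are fixed to the marginals (the fixture case); otherwise
#' they are sampled from the implied proportions. A patient owns one or two eye
#' records, never more.
#'
#' @param n_patients Number of patients.
#' @param n_eyes Number of eyes; must satisfy
#'   `n_patients <= n_eyes <= 2 * n_patients`.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param marginals Parameter set, see [default_marginals()].
#' @return A data.frame with one row per eye: `patient_id`, `eye_id`, `age`,
#'   `gender`, `erm_present`, `cmt_baseline`, `cmt_3month`, `iop`, `bcva`,
#'   `responder`.
#' @export
generate_cohort <- function(n_patients = 371L, n_eyes = 402L, seed = 1L,
                            marginals = default_marginals()) {
  if (n_eyes < n_patients) stopf("n_eyes (%d) < n_patients (%d)", n_eyes, n_patients)
  if (n_eyes > 2L * n_patients)
    stopf("n_eyes (%d) exceeds 2 eyes per patient (%d patients)", n_eyes, n_patients)
  gr <- marginals$groups
  n_total <- sum(vapply(gr, function(g) g$n, 1L))
  with_seed(seed, {
    if (n_patients == n_total) {
      grp <- rep(names(gr), times = vapply(gr, function(g) g$n, 1L))
      gender <- unlist(lapply(gr, function(g)
        c(rep("female", g$female), rep("male", g$male))), use.names = FALSE)
    } else {
      p_resp <- gr$responsive$n / n_total
      grp <- ifelse(runif(n_patients) < p_resp, "responsive", "nonresponsive")
      gender <- vapply(grp, function(g) {
        pf <- gr[[g]]$female / (gr[[g]]$female + gr[[g]]$male)
        if (runif(1) < pf) "female" else "male"
      }, "")
    }
    age <- vapply(seq_len(n_patients), function(i)
      rnorm_trunc(1, gr[[grp[i]]]$age[1], gr[[grp[i]]]$age[2], 18, 95), 1)
    two_eye <- rep(FALSE, n_patients)
    if (n_eyes > n_patients)
      two_eye[sample.int(n_patients, n_eyes - n_patients)] <- TRUE

    rows <- vector("list", n_eyes)
    ri <- 0L
    thr <- marginals$threshold
    for (i in seq_len(n_patients)) {
      pid <- sprintf("P%04d", i)
      sides <- if (two_eye[i]) c("OD", "OS") else "OD"
      g <- gr[[grp[i]]]
      for (s in sides) {
        base <- rnorm_trunc(1, g$cmt[1], g$cmt[2], 150, 1500)
        dc <- if (grp[i] == "responsive")
          rnorm_trunc(1, g$dcmt[1], g$dcmt[2], thr, 0.80)
        else
          rnorm_trunc(1, g$dcmt[1], g$dcmt[2], -0.60, thr - 0.005)
        m3 <- base * (1 - dc)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          patient_id = pid,
          eye_id = paste0(pid, "_", s),
          age = age[i],
          gender = gender[i],
          erm_present = runif(1) < g$erm_rate,
          cmt_baseline = base,
          cmt_3month = m3,
          iop = rnorm_trunc(1, g$iop[1], g$iop[2], 8, 30),
          bcva = rnorm_trunc(1, g$bcva[1], g$bcva[2], 0.01, 1.5),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    out$responder <- responder_label(out$cmt_baseline, out$cmt_3month)
    rownames(out) <- NULL
    out
  })
}

#' B-scan phantom geometry
#'
#' Knobs for the layered-retina phantom. `contrast` is the guaranteed minimum
#' mean-intensity separation between an IRC lesion and its surrounding band;
#' lesions are rendered deeper than that so that blur and noise cannot erode
#' the guarantee. `blur_sigma` and `noise_sd` are ranges sampled per image
#' (they drive the curriculum's image-quality factor); pass length-1 values to
#' pin them.
#'
#' @param height,width Image size in pixels (>= 32).
#' @param bg,band Background and retinal-band intensities in [0, 1].
#' @param contrast Minimum IRC-vs-band mean contrast.
#' @param n_irc Range (or single count) of IRC blobs for responder /
#'   non-responder eyes given as `list(responder=, nonresponder=)`.
#' @param srf_prob Probability of an SRF pocket per group.
#' @param erm "record" (use the record's flag), TRUE, or FALSE.
#' @param erm_len Length of the ERM curve in pixels.
#' @param erm_thickness 1 or 2 pixels.
#' @param blur_sigma,noise_sd Ranges sampled uniformly per image.
#' @param allow_overlap Permit lesion classes to overlap (default disjoint).
#' @return A geometry parameter list.
#' @export
bscan_geometry <- function(height = 128L, width = 128L, bg = 0.08,
                           band = 0.62, contrast = 0.40,
                           n_irc = list(responder = c(2L, 4L),
                                        nonresponder = c(0L, 2L)),
                           srf_prob = list(responder = 0.90,
                                           nonresponder = 0.15),
                           erm = "record", erm_len = NULL, erm_thickness = 1L,
                           blur_sigma = c(0, 0.9), noise_sd = c(0.01, 0.04),
                           allow_overlap = FALSE) {
  list(height = as.integer(height), width = as.integer(width), bg = bg,
       band = band, contrast = contrast, n_irc = n_irc, srf_prob = srf_prob,
       erm = erm, erm_len = erm_len, erm_thickness = as.integer(erm_thickness),
       blur_sigma = blur_sigma, noise_sd = noise_sd,
       allow_overlap = allow_overlap)
}

range_draw <- function(r) if (length(r) == 1L) r else runif(1, r[1], r[2])
count_draw <- function(r) if (length(r) == 1L) as.integer(r) else
  sample(seq.int(r[1], r[2]), 1L)

#' Generate a B-scan phantom with ground-truth lesion masks
#'
#' Renders horizontal bright retinal bands with a foveal dome; IRC as dark
#' ellipses inside the band, SRF as a dark dome beneath it, and ERM as a thin
#' bright curve on the inner surface. The returned binary masks cover exactly
#' the rendered lesion pixels (before blur/noise corruption of the image).
#' Lesion extent and count scale with the record's baseline CMT and response
#' group, so the images carry class signal.
#'
#' @param record One row of a cohort from [generate_cohort()].
#' @param geometry See [bscan_geometry()].
#' @param seed Integer seed.
#' @return A list: `image` (H x W matrix in [0, 1]), `masks` (named list of
#'   binary matrices `ERM`, `IRC`, `SRF`), `eye_id`, `modality = "OCT"`.
#' @export
generate_bscan <- function(record, geometry = bscan_geometry(), seed = 1L) {
  H <- geometry$height; W <- geometry$width
  if (H < 32L || W < 32L) stopf("B-scan size must be at least 32 x 32")
  with_seed(seed, {
    img <- matrix(geometry$bg, H, W)
    mask <- list(ERM = matrix(0L, H, W), IRC = matrix(0L, H, W),
                 SRF = matrix(0L, H, W))
    cols <- seq_len(W)

    # retinal band: inner surface with a foveal dip, thickness from CMT
    thick <- round(H * 0.22 * min(record$cmt_baseline, 900) / 430)
    thick <- max(round(H * 0.10), min(thick, round(H * 0.42)))
    top0 <- round(H * 0.30)
    dip <- round(H * 0.06)
    xc <- (cols - W / 2) / (W / 2)
    top <- pmax(2L, round(top0 + dip * exp(-(xc * 4)^2) + 2 * sin(xc * 3)))
    bot <- pmin(H - 2L, top + thick)
    for (j in cols) img[top[j]:bot[j], j] <- geometry$band

    grp <- if (isTRUE(record$responder)) "responder" else "nonresponder"

    # IRC: dark ellipses fully inside the band
    n_irc <- count_draw(geometry$n_irc[[grp]])
    irc_val <- geometry$band - 1.5 * geometry$contrast
    if (n_irc > 0) {
      for (b in seq_len(n_irc)) {
        ry <- max(2, round(runif(1, 0.03, 0.07) * H))
        rx <- max(3, round(runif(1, 0.05, 0.12) * W))
        if (2 * rx >= W || 2 * ry >= H)
          stopf("IRC lesion size exceeds image bounds")
        cx <- round(runif(1, rx + 2, W - rx - 2))
        cy <- round(runif(1, top[cx] + ry + 1, max(top[cx] + ry + 1, bot[cx] - ry - 1)))
        for (j in max(1, cx - rx):min(W, cx + rx)) {
          dy <- ry * sqrt(max(0, 1 - ((j - cx) / rx)^2))
          r1 <- max(top[j] + 1, round(cy - dy)); r2 <- min(bot[j] - 1, round(cy + dy))
          if (r1 <= r2) {
            img[r1:r2, j] <- irc_val
            mask$IRC[r1:r2, j] <- 1L
          }
        }
      }
    }

    # SRF: dark dome attached beneath the band
    if (runif(1) < geometry$srf_prob[[grp]]) {
      dep <- max(3, round(runif(1, 0.06, 0.12) * H))
      rx <- max(6, round(runif(1, 0.12, 0.25) * W))
      if (2 * rx >= W) stopf("SRF lesion size exceeds image bounds")
      cx <- round(runif(1, rx + 2, W - rx - 2))
      for (j in max(1, cx - rx):min(W, cx + rx)) {
        d <- round(dep * sqrt(max(0, 1 - ((j - cx) / rx)^2)))
        if (d >= 1) {
          r1 <- min(H, bot[j] + 1); r2 <- min(H, bot[j] + d)
          img[r1:r2, j] <- 0.12
          mask$SRF[r1:r2, j] <- 1L
        }
      }
    }

    # ERM: thin bright curve hovering on the inner surface
    draw_erm <- if (identical(geometry$erm, "record")) isTRUE(record$erm_present)
                else isTRUE(geometry$erm)
    if (draw_erm) {
      len <- if (is.null(geometry$erm_len)) round(0.5 * W) else geometry$erm_len
      if (len > W) stopf("ERM length %d exceeds image width %d", len, W)
      x0 <- if (len == W) 1L else round(runif(1, 1, W - len))
      for (j in x0:(x0 + len - 1L)) {
        r0 <- max(1L, top[j] - 2L)
        rr <- r0:max(1L, r0 - geometry$erm_thickness + 1L)
        img[rr, j] <- 0.95
        mask$ERM[rr, j] <- 1L
      }
    }

    sig <- range_draw(geometry$blur_sigma)
    nsd <- range_draw(geometry$noise_sd)
    img <- gauss_blur(img, sig)
    img <- clamp01(img + matrix(rnorm(H * W, 0, nsd), H, W))
    list(image = img, masks = mask, eye_id = record$eye_id, modality = "OCT")
  })
}

#' Ultra-widefield fundus phantom parameters
#'
#' @param height,width Image size.
#' @param speckle_rate Expected count of bright peripheral speckles added for
#'   non-responder eyes (emulating peripheral lesions, ischemic areas, laser
#'   scars that carry prognostic signal); 0 removes the class signal entirely.
#' @return Parameter list.
#' @export
uwf_params <- function(height = 128L, width = 128L, speckle_rate = 40) {
  list(height = as.integer(height), width = as.integer(width),
       speckle_rate = speckle_rate)
}

#' Generate an ultra-widefield fundus phantom
#'
#' A fundus-like disc with vessel strokes and an optic-disc highlight; for
#' non-responder records, bright speckles are scattered over the peripheral
#' annulus at `speckle_rate`, so the modality carries class signal.
#'
#' @param record One cohort row.
#' @param seed Integer seed.
#' @param params See [uwf_params()].
#' @return A list: `pixels` (H x W x 3 array in [0, 1]), `eye_id`,
#'   `modality = "UWF"`.
#' @export
generate_uwf <- function(record, seed = 1L, params = uwf_params()) {
  H <- params$height; W <- params$width
  with_seed(seed, {
    px <- array(0.02, c(H, W, 3))
    cy <- H / 2; cx <- W / 2; R <- 0.48 * min(H, W)
    rr <- outer(seq_len(H) - cy, rep(1, W)) ; cc <- outer(rep(1, H), seq_len(W) - cx)
    rad <- sqrt(rr^2 + cc^2)
    disc <- rad <= R
    fall <- pmax(0, 1 - (rad / R)^2)
    base <- c(0.55, 0.25, 0.08)
    for (ch in 1:3) {
      sl <- px[, , ch]
      sl[disc] <- base[ch] * (0.55 + 0.45 * fall[disc])
      px[, , ch] <- sl
    }
    # vessels: jittered radial walks from near the center
    for (v in seq_len(8L)) {
      ang <- runif(1, 0, 2 * pi)
      r0 <- 0.05 * R; pos <- c(cy + r0 * sin(ang), cx + r0 * cos(ang))
      dirv <- c(sin(ang), cos(ang))
      for (s in seq_len(round(R))) {
        dirv <- dirv + rnorm(2, 0, 0.15); dirv <- dirv / sqrt(sum(dirv^2))
        pos <- pos + dirv
        r <- round(pos[1]); c <- round(pos[2])
        if (r < 1 || r > H || c < 1 || c > W || rad[r, c] > R) break
        px[r, c, ] <- c(0.30, 0.08, 0.03)
      }
    }
    # optic disc highlight
    od <- sqrt((rr - 0.05 * H)^2 + (cc - 0.22 * W)^2) <= 0.06 * min(H, W)
    for (ch in 1:3) {
      sl <- px[, , ch]; sl[od & disc] <- c(0.85, 0.70, 0.40)[ch]
      px[, , ch] <- sl
    }
    # peripheral speckles for non-responders
    if (!isTRUE(record$responder) && params$speckle_rate > 0) {
      n <- rpois(1, params$speckle_rate)
      if (n > 0) for (s in seq_len(n)) {
        r <- runif(1, 0.30, 0.46) * min(H, W); a <- runif(1, 0, 2 * pi)
        y <- round(cy + r * sin(a)); x <- round(cx + r * cos(a))
        ys <- max(1, y - 1):min(H, y + 1); xs <- max(1, x - 1):min(W, x + 1)
        px[ys, xs, 1] <- 0.90; px[ys, xs, 2] <- 0.85; px[ys, xs, 3] <- 0.50
      }
    }
    px <- clamp01(px + array(rnorm(H * W * 3, 0, 0.015), c(H, W, 3)))
    list(pixels = px, eye_id = record$eye_id, modality = "UWF")
  })
}

# ---- disk formats -----------------------------------------------------------

#' Write / read phantom images and masks as PNG
#'
#' OCT images are written as 8-bit grayscale, UWF as 8-bit RGB. Lesion masks
#' are stored in a single 8-bit grayscale PNG holding raw label values
#' 0 = background, 1 = ERM, 2 = IRC, 3 = SRF (exactly invertible).
#'
#' @param img Matrix (grayscale) or H x W x 3 array.
#' @param path Output file.
#' @name phantom_io
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clamp01(img), target = path)
  invisible(path)
}

#' @rdname phantom_io
#' @param masks Named list of binary matrices (`ERM`, `IRC`, `SRF`).
#' @export
write_mask_png <- function(masks, path) {
  lab <- masks$ERM * 1L + masks$IRC * 2L + masks$SRF * 3L
  png::writePNG(lab / 255, target = path)
  invisible(path)
}

#' @rdname phantom_io
#' @export
read_mask_png <- function(path) {
  lab <- round(png::readPNG(path) * 255)
  list(ERM = (lab == 1) * 1L, IRC = (lab == 2) * 1L, SRF = (lab == 3) * 1L)
}

#' @rdname phantom_io
#' @export
read_image_png <- function(path) {
  png::readPNG(path)
}
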