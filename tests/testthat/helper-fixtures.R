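## Shared fixtures and independent oracles. All fixtures are built in code.

## Open cylindrical tube mesh (two boundary loops), uniform region/material.
cylinder_mesh <- function(r, z0 = -20, z1 = 40, nc = 48, nz = 25,
                          region = "LVOT", material = "WALL") {
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  zr <- seq(z0, z1, length.out = nz)
  v <- cbind(r * cos(rep(th, nz)), r * sin(rep(th, nz)), rep(zr, each = nc))
  idx <- function(i, j) (j - 1) * nc + ((i - 1) %% nc) + 1
  i <- rep(seq_len(nc), nz - 1)
  j <- rep(seq_len(nz - 1), each = nc)
  tr <- rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
              cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  surface_mesh(v, tr, rep(region, nrow(tr)), rep(material, nrow(tr)))
}

## Independent ray-casting oracle: loops over TRIANGLES, vectorised over
## RAYS (the implementation does the opposite), sharing no code path.
brute_force_raycast <- function(mesh, origins, dirs, tmax = Inf) {
  n_rays <- nrow(origins)
  best_t <- rep(Inf, n_rays)
  best_tri <- rep(NA_integer_, n_rays)
  v <- mesh$vertices
  tr <- mesh$triangles
  for (k in seq_len(nrow(tr))) {
    a <- v[tr[k, 1], ]; b <- v[tr[k, 2], ]; c3 <- v[tr[k, 3], ]
    e1 <- b - a; e2 <- c3 - a
    px <- dirs[, 2] * e2[3] - dirs[, 3] * e2[2]
    py <- dirs[, 3] * e2[1] - dirs[, 1] * e2[3]
    pz <- dirs[, 1] * e2[2] - dirs[, 2] * e2[1]
    det <- e1[1] * px + e1[2] * py + e1[3] * pz
    ok <- abs(det) > 1e-12
    inv <- ifelse(ok, 1 / det, 0)
    tx <- origins[, 1] - a[1]; ty <- origins[, 2] - a[2]
    tz <- origins[, 3] - a[3]
    u <- (tx * px + ty * py + tz * pz) * inv
    qx <- ty * e1[3] - tz * e1[2]
    qy <- tz * e1[1] - tx * e1[3]
    qz <- tx * e1[2] - ty * e1[1]
    w <- (dirs[, 1] * qx + dirs[, 2] * qy + dirs[, 3] * qz) * inv
    tt <- (e2[1] * qx + e2[2] * qy + e2[3] * qz) * inv
    eps <- 1e-9
    hit <- ok & u >= -eps & w >= -eps & (u + w) <= 1 + eps &
      tt > eps & tt <= tmax & tt < best_t
    best_t[hit] <- tt[hit]
    best_tri[hit] <- k
  }
  list(t = best_t, triangle = best_tri)
}

## Paired vectors with an exact sample Pearson correlation rho.
make_correlated_pairs <- function(n, rho, seed = 42) {
  set.seed(seed)
  x <- scale(stats::rnorm(n))[, 1]
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- e / stats::sd(e)
  y <- rho * x / stats::sd(x) + sqrt(1 - rho^2) * e
  list(x = x, y = y)
}

## Small deployed state on concentric cylinders for sealing tests:
## frame nominal radius r_frame deployed freely inside a lumen of radius
## r_anat (r_anat > r_frame gives a uniform gap).
cylinder_deployment <- function(r_frame = 10, r_anat = 12, size = 23) {
  prof <- data.frame(height = c(0, 47), radius = c(r_frame, r_frame))
  fp <- frame_params(size, nominal_profile = prof)
  fr <- crimp(build_frame(fp), 2 * r_frame - 4)
  an <- cylinder_mesh(r_anat, z0 = -15, z1 = 55, nc = 64, nz = 30)
  deploy(fr, an, depth = 6)
}

## One fast synthetic patient (shared by sealing / pipeline tests).
quick_patient <- function(seed = 7, morphology = "TAV") {
  spec <- cohort_spec(n_tav = as.integer(morphology == "TAV"),
                      n_bav0 = as.integer(morphology == "BAV0"),
                      n_bav1 = as.integer(morphology == "BAV1"),
                      seed = seed, mesh_resolution = c(64L, 40L))
  co <- sample_cohort(spec)
  set.seed(seed)
  cfg <- pipeline_config(cohort = spec)
  list(result = simulate_patient(co$params[[1]], co$table[1, ], cfg),
       covariates = co$table[1, ])
}
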