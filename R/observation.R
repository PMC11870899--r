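#' Raycast observations
#'
#' The agent emits `r` rays (r odd) on its horizontal plane, fanned evenly
#' over `angle_span` degrees and centred on its heading; columns are ordered
#' left to right, so the centre column is the ray pointing directly ahead.
#' Each ray reports the nearest solid or valenced intersection as an 8-row
#' column: rows 1-6 are one-hot object-category flags (positive goal,
#' negative goal/zone, immovable, movable, dispenser/button, sign board),
#' row 7 is a no-hit flag, and row 8 the hit distance normalised by the
#' 60-unit ray range (1 when nothing is hit). Transparent walls and tunnels
#' do register on raycasts; the arena's boundary fence does not, so rays can
#' escape unhit.
#'
#' @param world A `world_state`.
#' @param r Odd ray count (`>= 1`).
#' @param angle_span Fan width in degrees, in `(0, 360]`.
#' @return A `raycast_obs`: an 8 x r matrix with category row names.
#' @export
raycast_scan <- function(world, r = 45, angle_span = 60) {
  stopifnot(inherits(world, "world_state"))
  if (r < 1 || r %% 2 == 0) stop("ray count must be odd", call. = FALSE)
  if (angle_span <= 0 || angle_span > 360) {
    stop("angle span must be in (0, 360]", call. = FALSE)
  }
  ag <- world$bodies[[1]]
  angles <- if (r == 1) 0 else seq(-angle_span / 2, angle_span / 2, length.out = r)
  obs <- matrix(0, nrow = 8, ncol = r,
                dimnames = list(c(RAY_CATEGORIES, "no_hit", "distance"), NULL))
  dirs <- vapply(angles, function(a) heading_vec(ag$yaw + a), numeric(2))
  best_t <- rep(Inf, r)
  best_cat <- rep(NA_character_, r)
  for (o in world$bodies[-1]) {
    if (!o$solid && !o$zone) next
    t <- if (is_sphere(o)) {
      ray_circle_t(ag$x, ag$z, dirs, o$x, o$z, body_radius(o))
    } else {
      ray_rect_t(ag$x, ag$z, dirs, o)
    }
    upd <- which(t < best_t)
    if (length(upd)) {
      best_t[upd] <- t[upd]
      best_cat[upd] <- o$category
    }
  }
  hit <- is.finite(best_t) & best_t <= PHYS$ray_max
  obs["no_hit", !hit] <- 1
  obs["distance", ] <- ifelse(hit, best_t / PHYS$ray_max, 1)
  for (k in which(hit)) obs[best_cat[k], k] <- 1
  structure(obs, class = c("raycast_obs", "matrix", "array"))
}

# distance along each ray (columns of dirs) to a circle; Inf when missed
ray_circle_t <- function(ox, oz, dirs, cx, cz, r) {
  fx <- ox - cx; fz <- oz - cz
  b <- 2 * (dirs[1, ] * fx + dirs[2, ] * fz)
  c0 <- fx^2 + fz^2 - r^2
  disc <- b^2 - 4 * c0
  t <- rep(Inf, ncol(dirs))
  ok <- disc >= 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-b[ok] - sq) / 2
    t2 <- (-b[ok] + sq) / 2
    tt <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, Inf))
    t[ok] <- tt
  }
  t
}

# distance along each ray to a y-rotated rectangle footprint (2D slab test)
ray_rect_t <- function(ox, oz, dirs, o) {
  a <- deg2rad(o$yaw)
  # transform origin and directions into the body frame
  rx <- ox - o$x; rz <- oz - o$z
  lox <- rx * cos(a) - rz * sin(a)
  loz <- rx * sin(a) + rz * cos(a)
  ldx <- dirs[1, ] * cos(a) - dirs[2, ] * sin(a)
  ldz <- dirs[1, ] * sin(a) + dirs[2, ] * cos(a)
  hx <- o$sx / 2; hz <- o$sz / 2
  slab <- function(o1, d1, h) {
    tiny <- abs(d1) < 1e-12
    d1s <- ifelse(tiny, 1e-12, d1)
    t1 <- (-h - o1) / d1s
    t2 <- (h - o1) / d1s
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    lo[tiny] <- ifelse(abs(o1[tiny]) <= h, -Inf, Inf)
    hi[tiny] <- ifelse(abs(o1[tiny]) <= h, Inf, -Inf)
    list(lo = lo, hi = hi)
  }
  sx <- slab(rep(lox, ncol(dirs)), ldx, hx)
  sz <- slab(rep(loz, ncol(dirs)), ldz, hz)
  tmin <- pmax(sx$lo, sz$lo)
  tmax <- pmin(sx$hi, sz$hi)
  t <- ifelse(tmax >= pmax(tmin, 0) & tmax > 1e-9, pmax(tmin, 1e-9), Inf)
  t
}

#' Ray-grid camera observations
#'
#' A flat-shaded software renderer: a `k` x `k` grid of view rays is cast
#' from the agent's eye (60-degree field of view, pitch level with the
#' horizon), and each pixel takes the configured RGB colour of the nearest
#' opaque object, or the floor, boundary-fence, or sky colour. Transparent
#' objects and zones are invisible to the camera. With `grayscale = TRUE` the
#' image collapses to a `k` x `k` luminance matrix.
#'
#' @param world A `world_state`.
#' @param k Resolution, `4 <= k <= 512`.
#' @param grayscale Return luminance instead of RGB?
#' @return A `camera_obs`: a `k x k x 3` array in `[0, 255]`, or a `k x k`
#'   matrix when grayscale.
#' @export
render_camera <- function(world, k = 32, grayscale = FALSE) {
  stopifnot(inherits(world, "world_state"))
  if (k < 4 || k > 512) stop("camera resolution must satisfy 4 <= k <= 512", call. = FALSE)
  ag <- world$bodies[[1]]
  eye <- c(ag$x, ag$y + 0.5, ag$z)
  h <- heading_vec(ag$yaw)
  fwd <- c(h[1], 0, h[2])
  right <- c(h[2], 0, -h[1])
  up <- c(0, 1, 0)
  half_tan <- tan(deg2rad(30))
  px <- (seq_len(k) - 0.5) / k * 2 - 1
  uu <- rep(px, each = k) * half_tan          # column-major: u varies by column
  vv <- rep(rev(px), times = k) * half_tan    # v: top row looks up
  d <- rbind(fwd[1] + right[1] * uu + up[1] * vv,
             fwd[2] + right[2] * uu + up[2] * vv,
             fwd[3] + right[3] * uu + up[3] * vv)
  d <- d / rep(sqrt(colSums(d^2)), each = 3)
  n <- ncol(d)
  best_t <- rep(Inf, n)
  col_r <- rep(135, n); col_g <- rep(206, n); col_b <- rep(235, n)  # sky
  paint <- function(t, r, g, b) {
    upd <- which(t < best_t)
    if (length(upd)) {
      best_t[upd] <<- t[upd]
      col_r[upd] <<- r; col_g[upd] <<- g; col_b[upd] <<- b
    }
  }
  # floor
  dy <- d[2, ]
  tf <- ifelse(dy < -1e-9, -eye[2] / dy, Inf)
  paint(tf, 180, 180, 180)
  # boundary fences (height 2)
  for (w in list(c(1, 0), c(1, ARENA_SIZE), c(3, 0), c(3, ARENA_SIZE))) {
    ax <- w[1]; plane <- w[2]
    da <- d[ax, ]
    t <- ifelse(abs(da) > 1e-9, (plane - eye[ax]) / da, Inf)
    t[t <= 1e-9] <- Inf
    hy <- eye[2] + t * d[2, ]
    t[!(hy >= 0 & hy <= 2)] <- Inf
    oth <- if (ax == 1) 3 else 1
    ho <- eye[oth] + t * d[oth, ]
    t[!(ho >= 0 & ho <= ARENA_SIZE)] <- Inf
    paint(t, 245, 245, 245)
  }
  for (o in world$bodies[-1]) {
    if (!o$solid || o$zone) next
    info <- kind_info(o$kind)
    if (o$kind %in% c("WallTransparent", "CylinderTunnelTransparent")) next
    t <- if (is_sphere(o)) {
      cam_sphere_t(eye, d, c(o$x, body_center_y(o), o$z), body_radius(o))
    } else {
      cam_obb_t(eye, d, o)
    }
    paint(t, o$color$r, o$color$g, o$color$b)
  }
  img <- array(0, dim = c(k, k, 3))
  img[, , 1] <- matrix(col_r, k, k)
  img[, , 2] <- matrix(col_g, k, k)
  img[, , 3] <- matrix(col_b, k, k)
  if (grayscale) {
    out <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    return(structure(out, class = c("camera_obs", "matrix", "array")))
  }
  structure(img, class = c("camera_obs", "array"))
}

cam_sphere_t <- function(eye, d, c0, r) {
  f <- eye - c0
  b <- 2 * (d[1, ] * f[1] + d[2, ] * f[2] + d[3, ] * f[3])
  cc <- sum(f^2) - r^2
  disc <- b^2 - 4 * cc
  t <- rep(Inf, ncol(d))
  ok <- disc >= 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-b[ok] - sq) / 2
    t2 <- (-b[ok] + sq) / 2
    t[ok] <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, Inf))
  }
  t
}

cam_obb_t <- function(eye, d, o) {
  a <- deg2rad(o$yaw)
  ox <- eye[1] - o$x; oz <- eye[3] - o$z
  lox <- ox * cos(a) - oz * sin(a)
  loz <- ox * sin(a) + oz * cos(a)
  loy <- eye[2] - (o$y + o$sy / 2)
  ldx <- d[1, ] * cos(a) - d[3, ] * sin(a)
  ldz <- d[1, ] * sin(a) + d[3, ] * cos(a)
  ldy <- d[2, ]
  n <- ncol(d)
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  dims <- list(list(lox, ldx, o$sx / 2), list(loy, ldy, o$sy / 2),
               list(loz, ldz, o$sz / 2))
  for (dim in dims) {
    o1 <- dim[[1]]; d1 <- dim[[2]]; h <- dim[[3]]
    tiny <- abs(d1) < 1e-12
    d1s <- ifelse(tiny, 1e-12, d1)
    t1 <- (-h - o1) / d1s
    t2 <- (h - o1) / d1s
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    if (any(tiny)) {
      inside <- abs(o1) <= h   # origin component is a scalar here
      lo[tiny] <- if (inside) -Inf else Inf
      hi[tiny] <- if (inside) Inf else -Inf
    }
    tmin <- pmax(tmin, lo); tmax <- pmin(tmax, hi)
  }
  ifelse(tmax >= pmax(tmin, 0) & tmax > 1e-9, pmax(tmin, 1e-9), Inf)
}

#' Lights-out masking
#'
#' During a lights-out window every visual observation value is replaced with
#' zeros (for a human player this is a black screen); proprioceptive channels
#' are unaffected. Windows are either explicit `[start, end)` step intervals
#' or an alternating schedule with period `p` (lights on for the first `p`
#' steps, off for the next `p`, and so on). Masking is idempotent.
#'
#' @param obs A `raycast_obs`, `camera_obs`, or an observation bundle list.
#' @param schedule `NULL`, `list(intervals = list(c(start, end), ...))`, or
#'   `list(period = p)`.
#' @param step The current step.
#' @return The observation, zeroed if `step` is in a lights-out window.
#' @export
apply_lights_out <- function(obs, schedule, step) {
  if (!lights_out_active(schedule, step)) return(obs)
  zero_visual(obs)
}

lights_out_active <- function(schedule, step) {
  if (is.null(schedule)) return(FALSE)
  if (!is.null(schedule$period)) {
    return(floor(step / schedule$period) %% 2 == 1)
  }
  any(vapply(schedule$intervals,
             function(iv) step >= iv[1] && step < iv[2], logical(1)))
}

zero_visual <- function(obs) {
  if (inherits(obs, "raycast_obs") || inherits(obs, "camera_obs")) {
    obs[] <- 0
    return(obs)
  }
  if (is.list(obs)) {
    for (nm in intersect(names(obs), c("raycast", "camera"))) {
      if (!is.null(obs[[nm]])) obs[[nm]][] <- 0
    }
    return(obs)
  }
  obs
}

# the per-step proprioceptive bundle
proprio_obs <- function(world, health) {
  ag <- world$bodies[[1]]
  list(health = health,
       velocity = c(x = ag$vx, y = ag$vy, z = ag$vz),
       position = c(x = ag$x, y = ag$y, z = ag$z))
}
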