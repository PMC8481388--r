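# Small 3-D vector toolkit shared by the generators and the motif-geometry
# code. Everything works on plain numeric length-3 vectors / n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors, degrees in [0, 180]
vec_angle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# rotation matrix about unit axis u by angle (degrees), Rodrigues form
rotation_about <- function(u, angle_deg) {
  u <- unitv(u)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about(unitv(cross3(a, p)), 180))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# NeRF atom placement: position D such that |CD| = bond, angle(B,C,D) =
# angle_deg and dihedral(A,B,C,D) = dihedral_deg
place_atom <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  th <- deg2rad(angle_deg)
  ph <- deg2rad(dihedral_deg)
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               bond * sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# dihedral angle (degrees, signed, in (-180, 180]) of points A-B-C-D
dihedral4 <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# best-fit rigid transform (R, t) mapping point set P onto Q (Kabsch)
kabsch_transform <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

apply_transform <- function(X, R, t) {
  sweep(X %*% t(R), 2, t, "+")
}

# distance from points (n x 3) to the infinite line (anchor, unit dir)
point_line_distance <- function(X, anchor, dir) {
  dir <- unitv(dir)
  V <- sweep(X, 2, anchor)
  proj <- as.numeric(V %*% dir)
  sqrt(pmax(0, rowSums(V * V) - proj^2))
}
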