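# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# Evaluate `code` under a temporary RNG seed; NULL leaves the RNG alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  abort_if(!is.numeric(seed) || length(seed) != 1L || is.na(seed),
           "`seed` must be a single integer or NULL")
  withr::with_seed(as.integer(seed), code)
}

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  abort_if(n < 1e-12, "zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rotation matrix about unit axis `u` by `theta` radians (Rodrigues).
rotation_matrix <- function(u, theta) {
  u <- unit_vec(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# Optimal rotation (Kabsch) aligning `moving` (n x 3) onto `fixed` (n x 3),
# both already centred; returns R such that moving %*% R ~ fixed.
kabsch_rotation <- function(moving, fixed) {
  H <- crossprod(moving, fixed)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

wrap_angle_deg <- function(a) {
  a <- a %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

is_dna_sequence <- function(sequence) {
  nchar(sequence) > 0L &&
    all(strsplit(toupper(sequence), "")[[1]] %in% c("A", "C", "G", "T"))
}

check_dna_sequence <- function(sequence) {
  abort_if(!is.character(sequence) || length(sequence) != 1L,
           "`sequence` must be a single character string")
  abort_if(!is_dna_sequence(sequence),
           "`sequence` must be non-empty and contain only A, C, G, T")
  strsplit(toupper(sequence), "")[[1L]]
}

complement_base <- function(base) {
  c(A = "T", T = "A", G = "C", C = "G")[base]
}
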