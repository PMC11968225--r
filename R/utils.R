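# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Per-stage substreams are derived additively so that the stages of one
# scene do not share a stream (see derive_seed).
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Small named offsets keep stage streams distinct while staying in 32-bit
# integer range for any root seed the user supplies.
derive_seed <- function(seed, stage) {
  offs <- c(scaffold = 101L, cells = 211L, render = 307L, calipers = 401L,
            bands = 503L, pipeline = 601L)
  s <- (as.integer(seed) %% 1000000000L) + offs[[stage]]
  as.integer(s)
}

# Polynomial rolling hash of a serialized R object, as hex; used only to
# fingerprint configurations in run manifests.
object_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Coerce EBImage results back to plain matrices.
as_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Pixel-center coordinate of index i (1-based) in micrometres.
px_center_um <- function(i, pixel_size_um) (i - 0.5) * pixel_size_um

# Index of the pixel containing physical coordinate u (micrometres).
um_to_px <- function(u, pixel_size_um) pmax(1L, as.integer(ceiling(u / pixel_size_um)))
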