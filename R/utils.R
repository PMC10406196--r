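# internal helpers shared across modules

#' Null-default operator
#'
#' @param a,b `b` is returned when `a` is `NULL`.
#' @return `a` unless it is `NULL`, else `b`.
#' @name null-default
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ctt <- function(msg, class = "ctt_error") {
  rlang::abort(msg, class = c(class, "ctt_error"))
}

# exact 32-bit helpers on doubles (all intermediates stay below 2^53)
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
}
mul32 <- function(a, b) {
  (((a %/% 65536) * b %% 4294967296) * 65536 + (a %% 65536) * b) %% 4294967296
}

# splitmix32 avalanche: seeds derived from related inputs must not be
# affinely related (adjacent or arithmetic-progression integer seeds give
# correlated Mersenne-Twister streams)
splitmix32 <- function(x) {
  z <- (x + 2654435769) %% 4294967296
  z <- mul32(xor32(z, z %/% 65536), 569420461)
  z <- mul32(xor32(z, z %/% 32768), 1935289751)
  xor32(z, z %/% 32768)
}

# deterministic 31-bit sub-seed derivation; keeps every derived seed < 2^31
derive_seed <- function(seed, ...) {
  parts <- list(...)
  x <- splitmix32(as.double(seed) %% 4294967296)
  for (p in parts) {
    for (pi in p) {
      v <- if (is.character(pi)) sum(utf8ToInt(pi) * seq_along(utf8ToInt(pi)))
      else as.double(pi)
      x <- splitmix32(xor32(x, v %% 4294967296))
    }
  }
  as.integer(x %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a canonical JSON rendering; used for config provenance
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# 0-based C-order linear voxel id for 1-based (i, j, k) coordinates
vox_to_id <- function(coords, dim) {
  c0 <- coords - 1L
  c0[, 1L] * dim[2L] * dim[3L] + c0[, 2L] * dim[3L] + c0[, 3L]
}

id_to_vox <- function(ids, dim) {
  i <- ids %/% (dim[2L] * dim[3L])
  r <- ids %% (dim[2L] * dim[3L])
  j <- r %/% dim[3L]
  k <- r %% dim[3L]
  cbind(i, j, k) + 1L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

fisher_z <- function(r) atanh(r)
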