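# Embedded Gaussian basis sets (exponents / contraction coefficients for the
# elements used in the test systems).  Contraction coefficients refer to
# normalized primitives; contracted functions are renormalized numerically
# when the integrals are assembled.

.basis_library <- list(
  "sto-3g" = list(
    H = list(
      list(l = 0L, exps = c(3.42525091, 0.62391373, 0.16885540),
           coefs = c(0.15432897, 0.53532814, 0.44463454))
    ),
    C = list(
      list(l = 0L, exps = c(71.616837, 13.045096, 3.5305122),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    ),
    N = list(
      list(l = 0L, exps = c(99.106169, 18.052312, 4.8856602),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    ),
    O = list(
      list(l = 0L, exps = c(130.70932, 23.808861, 6.4436083),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    ),
    F = list(
      list(l = 0L, exps = c(166.67913, 30.360812, 8.2168207),
           coefs = c(0.15432897, 0.53532814, 0.44463454)),
      list(l = 0L, exps = c(6.4648032, 1.5022812, 0.4885885),
           coefs = c(-0.09996723, 0.39951283, 0.70011547)),
      list(l = 1L, exps = c(6.4648032, 1.5022812, 0.4885885),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    )
  ),
  "cc-pvdz" = list(
    H = list(
      list(l = 0L, exps = c(13.0100, 1.9620, 0.4446, 0.1220),
           coefs = c(0.019685, 0.137977, 0.478148, 0.501240)),
      list(l = 0L, exps = 0.1220, coefs = 1.0),
      list(l = 1L, exps = 0.7270, coefs = 1.0)
    ),
    C = list(
      list(l = 0L,
           exps = c(6665.0, 1000.0, 228.0, 64.71, 21.06, 7.495, 2.797,
                    0.5215, 0.1596),
           coefs = c(0.000692, 0.005329, 0.027077, 0.101718, 0.274740,
                     0.448564, 0.285074, 0.015204, -0.003191)),
      list(l = 0L,
           exps = c(6665.0, 1000.0, 228.0, 64.71, 21.06, 7.495, 2.797,
                    0.5215, 0.1596),
           coefs = c(-0.000146, -0.001154, -0.005725, -0.023312, -0.063955,
                     -0.149981, -0.127262, 0.544529, 0.580496)),
      list(l = 0L, exps = 0.1596, coefs = 1.0),
      list(l = 1L, exps = c(9.439, 2.002, 0.5456),
           coefs = c(0.038109, 0.209480, 0.508557)),
      list(l = 1L, exps = 0.1517, coefs = 1.0),
      list(l = 2L, exps = 0.5500, coefs = 1.0)
    ),
    N = list(
      list(l = 0L,
           exps = c(9046.0, 1357.0, 309.3, 87.73, 28.56, 10.21, 3.838,
                    0.7466, 0.2248),
           coefs = c(0.000700, 0.005389, 0.027406, 0.103207, 0.278723,
                     0.448540, 0.278238, 0.015440, -0.002864)),
      list(l = 0L,
           exps = c(9046.0, 1357.0, 309.3, 87.73, 28.56, 10.21, 3.838,
                    0.7466, 0.2248),
           coefs = c(-0.000153, -0.001208, -0.005992, -0.024544, -0.067459,
                     -0.158078, -0.121831, 0.549003, 0.578815)),
      list(l = 0L, exps = 0.2248, coefs = 1.0),
      list(l = 1L, exps = c(13.55, 2.917, 0.7973),
           coefs = c(0.039919, 0.217169, 0.510319)),
      list(l = 1L, exps = 0.2185, coefs = 1.0),
      list(l = 2L, exps = 0.8170, coefs = 1.0)
    ),
    O = list(
      list(l = 0L,
           exps = c(11720.0, 1759.0, 400.8, 113.7, 37.03, 13.27, 5.025,
                    1.013, 0.3023),
           coefs = c(0.000710, 0.005470, 0.027837, 0.104800, 0.283062,
                     0.448719, 0.270952, 0.015458, -0.002585)),
      list(l = 0L,
           exps = c(11720.0, 1759.0, 400.8, 113.7, 37.03, 13.27, 5.025,
                    1.013, 0.3023),
           coefs = c(-0.000160, -0.001263, -0.006267, -0.025716, -0.070924,
                     -0.165411, -0.116955, 0.557368, 0.572759)),
      list(l = 0L, exps = 0.3023, coefs = 1.0),
      list(l = 1L, exps = c(17.70, 3.854, 1.046),
           coefs = c(0.043018, 0.228913, 0.508728)),
      list(l = 1L, exps = 0.2753, coefs = 1.0),
      list(l = 2L, exps = 1.1850, coefs = 1.0)
    ),
    F = list(
      list(l = 0L,
           exps = c(14710.0, 2207.0, 502.8, 142.6, 46.47, 16.70, 6.356,
                    1.316, 0.3897),
           coefs = c(0.000721, 0.005553, 0.028267, 0.106444, 0.286814,
                     0.448641, 0.264761, 0.015333, -0.002332)),
      list(l = 0L,
           exps = c(14710.0, 2207.0, 502.8, 142.6, 46.47, 16.70, 6.356,
                    1.316, 0.3897),
           coefs = c(-0.000165, -0.001308, -0.006495, -0.026691, -0.073690,
                     -0.170776, -0.112327, 0.562814, 0.568778)),
      list(l = 0L, exps = 0.3897, coefs = 1.0),
      list(l = 1L, exps = c(22.67, 4.977, 1.347),
           coefs = c(0.044878, 0.235718, 0.508521)),
      list(l = 1L, exps = 0.3471, coefs = 1.0),
      list(l = 2L, exps = 1.6400, coefs = 1.0)
    )
  )
)

#' List available basis sets
#' @return character vector of basis-set names.
#' @export
available_bases <- function() names(.basis_library)

# double factorial (2l-1)!! for l >= 0
.dfact2lm1 <- function(l) if (l <= 1) 1 else prod(seq(2 * l - 1, 1, by = -2))

# primitive normalization for the (l,0,0)-type cartesian component
.prim_norm <- function(l, alpha) {
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(.dfact2lm1(l))
}

# Build the shell list (centers in bohr, coefficients premultiplied by the
# primitive norms) for a molecule, plus bookkeeping of cartesian/spherical
# dimensions and the cartesian->spherical coefficient blocks.
.build_shells <- function(mol, basis) {
  bname <- tolower(basis)
  blib <- .basis_library[[bname]]
  if (is.null(blib)) {
    stop("unknown basis set '", basis, "'; available: ",
         paste(names(.basis_library), collapse = ", "))
  }
  missing_el <- setdiff(unique(mol$atoms), names(blib))
  if (length(missing_el) > 0) {
    stop("basis '", basis, "' has no parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  }
  shells <- list()
  for (i in seq_along(mol$atoms)) {
    el <- mol$atoms[i]
    center <- mol$coordinates[i, ] * .angstrom
    for (sh in blib[[el]]) {
      shells[[length(shells) + 1]] <- list(
        l = sh$l,
        exps = as.numeric(sh$exps),
        coefs = as.numeric(sh$coefs) * .prim_norm(sh$l, as.numeric(sh$exps)),
        center = as.numeric(center)
      )
    }
  }
  shells
}

# solid-harmonic combination coefficients over raw cartesian monomials,
# rows = cartesian components, cols = spherical components (overall row/col
# scale fixed later by numerical normalization)
.c2s_block <- function(l) {
  if (l == 0L) return(matrix(1, 1, 1))
  if (l == 1L) return(diag(3))
  if (l == 2L) {
    # cart order xx, xy, xz, yy, yz, zz; sph order m = -2,-1,0,+1,+2
    m <- matrix(0, 6, 5)
    m[2, 1] <- 1                       # xy
    m[5, 2] <- 1                       # yz
    m[c(1, 4, 6), 3] <- c(-1, -1, 2)   # 2zz - xx - yy
    m[3, 4] <- 1                       # xz
    m[c(1, 4), 5] <- c(1, -1)          # xx - yy
    return(m)
  }
  stop("angular momentum ", l, " not supported")
}

# full cartesian -> normalized spherical transformation matrix
.c2s_matrix <- function(shells, S_cart) {
  blocks <- lapply(shells, function(sh) .c2s_block(sh$l))
  ncart <- vapply(blocks, nrow, 1L)
  nsph <- vapply(blocks, ncol, 1L)
  B <- matrix(0, sum(ncart), sum(nsph))
  ro <- c(0, cumsum(ncart))
  co <- c(0, cumsum(nsph))
  for (k in seq_along(blocks)) {
    B[(ro[k] + 1):ro[k + 1], (co[k] + 1):co[k + 1]] <- blocks[[k]]
  }
  d <- diag(t(B) %*% S_cart %*% B)
  B %*% diag(1 / sqrt(d), ncol(B))
}
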