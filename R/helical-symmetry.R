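#' Helical symmetry
#'
#' A helical lattice is described by the rotation (`twist_deg`, signed;
#' negative = left-handed) and axial translation (`rise_ang`, Angstrom)
#' relating consecutive subunits, optionally combined with an n-fold point
#' group rotation `Cn` about the helix axis.
#'
#' @param twist_deg rotation per subunit in degrees, in `[-360, 360]`.
#' @param rise_ang axial rise per subunit in Angstrom (> 0).
#' @param cn_order integer point-group order (>= 1).
#' @return object of class `helical_symmetry`.
#' @examples
#' helical_symmetry(-101.1, 5.1)          # left-handed 1-start
#' helical_symmetry(-53.6, 16.8, cn_order = 3)
#' @export
helical_symmetry <- function(twist_deg, rise_ang, cn_order = 1L) {
  if (!is.finite(twist_deg) || abs(twist_deg) > 360)
    stop("twist_deg must be finite with |twist| <= 360")
  if (!is.finite(rise_ang) || rise_ang <= 0)
    stop("invalid helical symmetry: rise_ang must be > 0")
  cn_order <- as.integer(cn_order)
  if (is.na(cn_order) || cn_order < 1L) stop("cn_order must be an integer >= 1")
  structure(list(twist_deg = twist_deg, rise_ang = rise_ang,
                 cn_order = cn_order),
            class = "helical_symmetry")
}

#' @export
format.helical_symmetry <- function(x, ...) {
  hand <- if (x$twist_deg < 0) "left-handed" else "right-handed"
  sprintf("helical symmetry: twist %.4g deg (%s), rise %.4g A, C%d",
          x$twist_deg, hand, x$rise_ang, x$cn_order)
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

as_helical_symmetry <- function(x) {
  if (inherits(x, "helical_symmetry")) return(x)
  if (is.numeric(x) && length(x) %in% 2:3)
    return(helical_symmetry(x[1], x[2], if (length(x) == 3) x[3] else 1L))
  stop("cannot interpret as helical symmetry")
}

#' Enumerate helical symmetry operators
#'
#' Operator `k` (combined with point-group index `j`) rotates by
#' `k*twist + j*360/cn` degrees and translates by `k*rise` Angstrom along
#' the axis.  Ordering is k-major, j-minor.
#'
#' @param sym a [helical_symmetry()].
#' @param k_min,k_max integer operator range (`k_min <= k_max`).
#' @return data.frame with columns `k`, `j`, `rotation_deg`,
#'   `translation_ang`.
#' @export
symmetry_operators <- function(sym, k_min = 0L, k_max = 0L) {
  sym <- as_helical_symmetry(sym)
  if (k_min > k_max) stop("k_min must be <= k_max")
  k <- rep(seq.int(k_min, k_max), each = sym$cn_order)
  j <- rep(seq_len(sym$cn_order) - 1L, times = k_max - k_min + 1L)
  data.frame(k = k, j = j,
             rotation_deg = k * sym$twist_deg + j * 360 / sym$cn_order,
             translation_ang = k * sym$rise_ang)
}

#' Pitch of the 1-start helix
#'
#' The 1-start helix connects each subunit to its successor; its pitch is
#' `(360/|twist|) * rise` Angstrom and sets the spacing of the `|n| = 1`
#' layer line.
#'
#' @param sym a [helical_symmetry()].
#' @return pitch in Angstrom.
#' @examples
#' one_start_pitch(helical_symmetry(-101.1, 5.1))  # ~18.2 A
#' @export
one_start_pitch <- function(sym) {
  sym <- as_helical_symmetry(sym)
  if (sym$twist_deg == 0) stop("undefined pitch: twist is zero")
  (360 / abs(sym$twist_deg)) * sym$rise_ang
}

#' Predict layer lines from the helical selection rule
#'
#' Axial layer-line frequencies follow the selection rule
#' `z = (n*twist/360 + m)/rise` with the Bessel order `n` restricted to
#' multiples of the point-group order.  Only `z >= 0` is reported (Friedel
#' symmetry makes negative frequencies redundant).  When `radius_ang` is
#' given, the radial frequency of the first intensity maximum of each line
#' (`peak_radius`) is evaluated from the first maximum of `|J_n|`.
#'
#' @param sym a [helical_symmetry()].
#' @param max_abs_n,max_abs_m search bounds on the Bessel order and axial
#'   repeat index.
#' @param z_max maximum axial frequency kept, 1/Angstrom.
#' @param radius_ang optional helical radius of the subunit (Angstrom) used
#'   to fill `peak_radius`.
#' @return data.frame sorted by `z_freq` with columns `z_freq`, `bessel_n`,
#'   `order_m`, `spacing_ang` (= 1/z, `Inf` on the equator) and
#'   `peak_radius` (NA unless `radius_ang` given; 0 for n = 0).
#' @examples
#' layer_lines(helical_symmetry(-101.1, 5.1), z_max = 0.1)
#' @export
layer_lines <- function(sym, max_abs_n = 3L, max_abs_m = 2L, z_max = 0.25,
                        radius_ang = NULL) {
  sym <- as_helical_symmetry(sym)
  if (!is.finite(z_max) || z_max <= 0) stop("z_max must be > 0")
  if (sym$rise_ang <= 0) stop("invalid helical symmetry: non-positive rise")
  n <- seq.int(-max_abs_n, max_abs_n)
  n <- n[n %% sym$cn_order == 0]
  grid <- expand.grid(bessel_n = n, order_m = seq.int(-max_abs_m, max_abs_m))
  z <- (grid$bessel_n * sym$twist_deg / 360 + grid$order_m) / sym$rise_ang
  keep <- z >= -1e-12 & z <= z_max
  out <- data.frame(z_freq = pmax(z[keep], 0),
                    bessel_n = grid$bessel_n[keep],
                    order_m = grid$order_m[keep])
  out <- out[order(out$z_freq, abs(out$bessel_n)), , drop = FALSE]
  out$spacing_ang <- ifelse(out$z_freq > 0, 1 / out$z_freq, Inf)
  out$peak_radius <- NA_real_
  if (!is.null(radius_ang)) {
    stopifnot(radius_ang > 0)
    out$peak_radius <- vapply(out$bessel_n, function(nn) {
      if (nn == 0) 0 else bessel_first_max(abs(nn)) / (2 * pi * radius_ang)
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

# cache of first-maximum arguments of |J_n|
.bessel_cache <- new.env(parent = emptyenv())

#' Argument of the first maximum of `|J_n|`
#'
#' Located numerically by golden-section maximization on a bracket known to
#' contain the first extremum (x1(1) = 1.8412).
#' @param n non-negative integer Bessel order.
#' @return first-maximum argument of `|J_n(x)|` (0 for n = 0).
#' @export
bessel_first_max <- function(n) {
  n <- as.integer(abs(n))
  if (n == 0L) return(0)
  key <- as.character(n)
  if (!is.null(.bessel_cache[[key]])) return(.bessel_cache[[key]])
  up <- n + 2 + 2 * n^(1 / 3)
  x1 <- optimize(function(x) besselJ(x, n), c(max(n * 0.5, 1e-3), up),
                 maximum = TRUE, tol = 1e-8)$maximum
  .bessel_cache[[key]] <- x1
  x1
}

#' Out-of-plane tilt that collapses a layer-line peak onto the meridian
#'
#' An off-meridional layer line (Bessel order `n != 0`) at axial frequency
#' `z` peaks at radial frequency `R = x1(|n|)/(2*pi*r)` where `r` is the
#' helical radius of the subunit.  In the power spectrum of a projection
#' tilted out of plane by `tau = atan(R/z)` that peak lands on the meridian
#' and can be mistaken for an n = 0 line.
#'
#' @param line one row of [layer_lines()] output, or a list with `z_freq`
#'   and `bessel_n`.
#' @param subunit_radius helical radius of the subunit in Angstrom.
#' @return collapse tilt in degrees.
#' @examples
#' ll <- layer_lines(helical_symmetry(-101.1, 5.1), z_max = 0.06)
#' line <- ll[ll$bessel_n == -1 & ll$order_m == 0, ]
#' collapse_tilt(line, subunit_radius = 33.5)  # ~9 degrees
#' @export
collapse_tilt <- function(line, subunit_radius) {
  z <- line$z_freq[1]; n <- line$bessel_n[1]
  if (!is.finite(subunit_radius) || subunit_radius <= 0)
    stop("subunit_radius must be > 0")
  if (n == 0) stop("no collapse: an n = 0 line is already meridional")
  if (!is.finite(z) || z <= 0) stop("z_freq must be > 0")
  r_peak <- bessel_first_max(abs(n)) / (2 * pi * subunit_radius)
  atan(r_peak / z) * 180 / pi
}

#' Enumerate candidate helical symmetries from observed layer lines
#'
#' Every assignment of a Bessel order `n` (from each line's allowed set,
#' restricted to multiples of the candidate point-group order) and an axial
#' repeat index `m` to each observed line yields a linear system
#' `z_i * rise - n_i * twist/360 = m_i` in (rise, twist).  Determined
#' systems are solved and kept when they reproduce every observed frequency
#' within `tol_z`; when the twist is unconstrained (all assigned `n` are 0,
#' or a single line), solutions are expanded over `twist_grid`.  Because
#' layer-line positions cannot fix the hand, both signs of the twist are
#' returned.  Near-duplicate solutions (within 0.5 deg / 0.1 A) are merged.
#'
#' @param observed list of observed lines, each `list(z_freq =, allowed_n =)`
#'   (equator entries with `z_freq` ~ 0 are ignored as unconstraining).
#' @param cn_candidates integer point-group orders to try.
#' @param max_abs_m bound on the axial repeat index.
#' @param tol_z match tolerance on z, 1/Angstrom (default one Fourier voxel
#'   of a 192 px box at 2.3 A/px).
#' @param twist_grid twist values (degrees > 0) used when the observations
#'   leave the twist free; `NULL` (default) reports such families as a
#'   single entry with `twist_deg = NA`.
#' @param rise_range admissible rise range in Angstrom.
#' @param dedup_twist,dedup_rise merge tolerances for duplicate solutions.
#' @return data.frame with columns `twist_deg`, `rise_ang`, `cn` (one row
#'   per candidate; empty when nothing fits).
#' @export
candidate_symmetries <- function(observed, cn_candidates = 1:3,
                                 max_abs_m = 2L,
                                 tol_z = 1 / (192 * 2.3),
                                 twist_grid = NULL,
                                 rise_range = c(1, 500),
                                 dedup_twist = 0.5, dedup_rise = 0.1) {
  if (length(observed) < 1L) stop("at least one observed line is required")
  lines <- Filter(function(l) l$z_freq > tol_z, observed)
  sols <- data.frame(twist_deg = numeric(), rise_ang = numeric(),
                     cn = integer())
  add <- function(tw, ri, cn) {
    if (!is.finite(ri) || ri < rise_range[1] || ri > rise_range[2]) return()
    if (is.finite(tw)) {
      tw <- ((tw + 180) %% 360) - 180          # canonical (-180, 180]
      if (tw == -180) tw <- 180
      sols[nrow(sols) + 1L, ] <<- list(tw, ri, cn)
      sols[nrow(sols) + 1L, ] <<- list(-tw, ri, cn)   # both hands
    } else {
      sols[nrow(sols) + 1L, ] <<- list(NA_real_, ri, cn)
    }
  }
  check_all <- function(tw, ri, ns, ms) {
    zp <- (ns * tw / 360 + ms) / ri
    all(abs(zp - vapply(lines, `[[`, numeric(1), "z_freq")) <= tol_z)
  }
  for (cn in cn_candidates) {
    allowed <- lapply(lines, function(l) l$allowed_n[l$allowed_n %% cn == 0])
    if (length(allowed) > 0 && any(vapply(allowed, length, 1L) == 0L)) next
    if (length(lines) == 0L) next
    pairs <- lapply(allowed, function(ns)
      expand.grid(n = ns, m = seq.int(-max_abs_m, max_abs_m)))
    combo <- do.call(expand.grid,
                     c(lapply(pairs, function(p) seq_len(nrow(p))),
                       list(KEEP.OUT.ATTRS = FALSE)))
    z <- vapply(lines, `[[`, numeric(1), "z_freq")
    for (r in seq_len(nrow(combo))) {
      ns <- mapply(function(p, i) p$n[i], pairs, as.integer(combo[r, ]))
      ms <- mapply(function(p, i) p$m[i], pairs, as.integer(combo[r, ]))
      A <- cbind(z, -ns / 360)
      qrA <- qr(A)
      if (qrA$rank == 2L) {
        th <- qr.coef(qrA, ms)                 # (rise, twist)
        if (!all(is.finite(th)) || th[1] <= 0 || abs(th[2]) > 540) next
        if (check_all(th[2], th[1], ns, ms)) add(th[2], th[1], cn)
      } else if (all(ns == 0)) {
        ok <- ms != 0 & (ms / z) > 0
        if (!any(ok)) next
        ri <- (ms / z)[which(ok)[1]]
        if (!check_all(0, ri, ns, ms)) next
        if (is.null(twist_grid)) add(NA_real_, ri, cn)
        else for (tw in twist_grid) add(tw, ri, cn)
      } else if (length(lines) == 1L) {
        # one equation z*rise - n*twist/360 = m: sweep twist, solve rise
        tg <- twist_grid
        if (is.null(tg)) { add(NA_real_, ms[1] / z[1], cn); next }
        for (tw in tg) {
          ri <- (ms[1] + ns[1] * tw / 360) / z[1]
          if (is.finite(ri) && ri > 0) add(tw, ri, cn)
        }
      }
    }
  }
  if (nrow(sols) == 0L) return(sols)
  key <- paste(sols$cn,
               ifelse(is.na(sols$twist_deg), "free",
                      round(sols$twist_deg / dedup_twist)),
               round(sols$rise_ang / dedup_rise))
  sols <- sols[!duplicated(key), , drop = FALSE]
  rownames(sols) <- NULL
  sols
}

#' Serialize / read symmetry and layer-line tables as TSV
#' @param x data.frame (layer-line table or symmetry table).
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
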