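#' Track discretization
#'
#' A linear track of length `L` divided into equal bins of size `x_res`.
#' The capacity formulas assume periodic boundary conditions (a circular
#' track), which avoids finite-size edge effects.
#'
#' @param L_m Track length (m).
#' @param x_res_m Spatial resolution / bin size (m); must divide `L_m`.
#' @param circular Periodic boundary conditions (default `TRUE`).
#' @return Object of class `track_discretization` with `L`, `x_res`,
#'   `n_bins`, `circular`.
#' @export
track_discretization <- function(L_m, x_res_m, circular = TRUE) {
  stopifnot(L_m > 0, x_res_m > 0)
  nb <- L_m / x_res_m
  if (abs(nb - round(nb)) > 1e-9) stop("x_res must divide L")
  structure(list(L = L_m, x_res = x_res_m, n_bins = as.integer(round(nb)),
                 circular = isTRUE(circular)),
            class = "track_discretization")
}

#' Exclusion-zone constraint
#'
#' Minimum separation `D` (about one place-field size) between field
#' centers of place cells coupled to the same interneuron.
#'
#' @param D_m Zone size (m).
#' @param x_res_m Bin size (m); must divide `D_m`.
#' @return Object of class `exclusion_constraint` with `D` and `n_d` (bins).
#' @export
exclusion_constraint <- function(D_m, x_res_m) {
  stopifnot(D_m > 0, x_res_m > 0)
  nd <- D_m / x_res_m
  if (abs(nd - round(nd)) > 1e-9) stop("x_res must divide D")
  structure(list(D = D_m, n_d = as.integer(round(nd))),
            class = "exclusion_constraint")
}

#' Capacity calculation parameters
#'
#' @param n_pyr,n_int Population sizes.
#' @param fields_per_cell Average number of place fields per pyramidal cell
#'   (`F`, may be below or above 1); the number of fields placed is
#'   `round(F * n_pyr)`.
#' @param assembly_size Cells per assembly (`n <= n_int`), optional.
#' @param sequence_length Assemblies per phase sequence (`m`), optional
#'   (`m*n <= n_int`).
#' @return Object of class `capacity_params`.
#' @export
capacity_params <- function(n_pyr, n_int, fields_per_cell = 1,
                            assembly_size = NULL, sequence_length = NULL) {
  stopifnot(n_pyr >= 1, n_int >= 1, fields_per_cell > 0)
  if (!is.null(assembly_size) && assembly_size > n_int)
    stop("assembly_size exceeds number of interneurons")
  if (!is.null(sequence_length) && !is.null(assembly_size) &&
      sequence_length * assembly_size > n_int)
    stop("sequence_length * assembly_size exceeds interneuron pool")
  structure(list(n_pyr = n_pyr, n_int = n_int,
                 fields_per_cell = fields_per_cell,
                 assembly_size = assembly_size,
                 sequence_length = sequence_length),
            class = "capacity_params")
}

#' Place-field map container
#'
#' @param bins 0-based bin index per active cell.
#' @param interneuron 1-based interneuron index per active cell.
#' @param track A [track_discretization()].
#' @param constraint Optional [exclusion_constraint()].
#' @return Object of class `place_field_map`.
#' @export
place_field_map <- function(bins, interneuron, track, constraint = NULL) {
  stopifnot(inherits(track, "track_discretization"),
            length(bins) == length(interneuron),
            all(bins >= 0), all(bins < track$n_bins))
  structure(list(bins = as.integer(bins),
                 interneuron = as.integer(interneuron), track = track,
                 constraint = constraint), class = "place_field_map")
}

#' Random place-field map
#'
#' Each active cell's field center is drawn independently and uniformly
#' over the track bins; the exclusion constraint is deliberately not
#' enforced (random maps may violate it).
#'
#' @param n_active Number of active cells.
#' @param n_int Number of interneurons; cells are assigned to interneurons
#'   in equal contiguous blocks.
#' @param track A [track_discretization()].
#' @param seed RNG seed.
#' @param constraint Optional [exclusion_constraint()] to attach (for later
#'   [verify_map()] calls); not enforced.
#' @return A [place_field_map()].
#' @export
random_map <- function(n_active, n_int, track, seed = 1L, constraint = NULL) {
  stopifnot(n_active >= 0)
  set.seed(as.integer(seed))
  bins <- if (n_active) sample.int(track$n_bins, n_active, replace = TRUE) - 1L
          else integer(0)
  interneuron <- rep(seq_len(n_int), length.out = max(n_active, 0))
  interneuron <- sort(interneuron)[seq_len(n_active)]
  place_field_map(bins, interneuron, track, constraint)
}

#' Optimal (minimum-overlap) place-field map
#'
#' Field centers are equally spaced so that the whole population uniformly
#' covers the track, with cells assigned to interneurons round-robin; cells
#' sharing an interneuron are then equally spaced at the maximum possible
#' separation `L/(n_active/n_int)`.
#'
#' @param n_active Number of active cells (`n_int` must divide it).
#' @param n_int Number of interneurons.
#' @param track A [track_discretization()].
#' @param constraint Optional [exclusion_constraint()] to attach.
#' @return A [place_field_map()].
#' @export
optimal_map <- function(n_active, n_int, track, constraint = NULL) {
  if (n_active %% n_int != 0)
    stop("n_int must divide n_active for an optimal map")
  i <- seq_len(n_active) - 1L
  bins <- as.integer(floor(i * track$n_bins / n_active))
  interneuron <- (i %% n_int) + 1L
  place_field_map(bins, interneuron, track, constraint)
}

#' Field centers of a map in meters
#' @param map A [place_field_map()].
#' @return Numeric vector of field-center positions (bin centers, m).
#' @export
map_centers_m <- function(map) (map$bins + 0.5) * map$track$x_res

# circular bin distance
.circ_dist <- function(b1, b2, n_bins, circular = TRUE) {
  d <- abs(b1 - b2)
  if (circular) pmin(d, n_bins - d) else d
}

#' Verify a map against the exclusion constraint
#'
#' Returns all pairs of same-interneuron cells that violate the constraint.
#' Two conventions are exposed: `"min_distance"` (default; a violation is a
#' circular bin distance strictly below `n_d`) and `"block"` (the
#' counting-formula convention: each field forbids a contiguous block of
#' `n_d` bins centered on its own, with the extra bin clockwise for even
#' `n_d`).
#'
#' @param map A [place_field_map()] with a constraint attached (or pass
#'   `constraint`).
#' @param constraint Optional [exclusion_constraint()] overriding the map's.
#' @param exclusion `"min_distance"` or `"block"`.
#' @return Data frame with columns `cell_i`, `cell_j`, `distance_bins` (one
#'   row per violating pair; zero rows if none).
#' @export
verify_map <- function(map, constraint = NULL,
                       exclusion = c("min_distance", "block")) {
  exclusion <- match.arg(exclusion)
  if (is.null(constraint)) constraint <- map$constraint
  stopifnot(inherits(constraint, "exclusion_constraint"))
  nd <- constraint$n_d
  nb <- map$track$n_bins
  viol <- list()
  n <- length(map$bins)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (map$interneuron[i] != map$interneuron[j]) next
      bad <- if (exclusion == "min_distance") {
        .circ_dist(map$bins[i], map$bins[j], nb, map$track$circular) < nd
      } else {
        .in_block(map$bins[i], map$bins[j], nd, nb) ||
          .in_block(map$bins[j], map$bins[i], nd, nb)
      }
      if (bad)
        viol[[length(viol) + 1]] <- data.frame(
          cell_i = i, cell_j = j,
          distance_bins = .circ_dist(map$bins[i], map$bins[j], nb,
                                     map$track$circular))
    }
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(cell_i = integer(0), cell_j = integer(0),
                  distance_bins = integer(0))
}

# is bin b inside the block of nd bins centered on bin b0?
# nd odd: offsets -(nd-1)/2 .. (nd-1)/2; nd even: -(nd/2-1) .. nd/2
.in_block <- function(b0, b, nd, n_bins) {
  off <- ((b - b0) %% n_bins)
  off[off > n_bins / 2] <- off[off > n_bins / 2] - n_bins
  lo <- -floor((nd - 1) / 2)
  hi <- ceiling((nd - 1) / 2) + if (nd %% 2 == 0) 1 else 0
  if (nd %% 2 == 0) { lo <- -(nd / 2 - 1); hi <- nd / 2 }
  off >= lo & off <= hi
}

#' Density bound on active place cells
#'
#' Maximum fraction `F` of pyramidal cells that can express place fields in
#' one map without same-interneuron overlap: `F < (NI/Np)*(L/D)`.
#'
#' @param n_int,n_pyr Population sizes.
#' @param L_m Track length (m).
#' @param D_m Exclusion-zone size (m).
#' @return The bound `F_max`.
#' @export
density_bound <- function(n_int, n_pyr, L_m, D_m) {
  stopifnot(n_int >= 1, n_pyr >= 1, L_m > 0, D_m > 0)
  (n_int / n_pyr) * (L_m / D_m)
}

.n_fields <- function(params) as.integer(round(params$fields_per_cell * params$n_pyr))

#' Number of constraint-satisfying maps (pre-Stirling form)
#'
#' Evaluates the sequential-counting expression for the number of distinct
#' maps of `round(F*Np)` place fields onto the circular track: the product
#' over fields of `(Np*Nbins - (i-1)*(Np/NI)*Nd)` divided by `(F*Np)!`,
#' computed in log space (log-gamma). For small instances the exact count
#' (as a double, exact below 2^53) is also available.
#'
#' @param params A [capacity_params()].
#' @param track A [track_discretization()].
#' @param constraint An [exclusion_constraint()].
#' @param log Return the natural log (default); if `FALSE`, the count
#'   itself (only meaningful for small instances).
#' @return Natural log of the number of maps (or the count).
#' @export
exact_map_count <- function(params, track, constraint, log = TRUE) {
  M <- .n_fields(params)
  stopifnot(M >= 1)
  per_prior <- params$n_pyr / params$n_int * constraint$n_d
  factors <- params$n_pyr * track$n_bins - (seq_len(M) - 1) * per_prior
  if (any(factors <= 0))
    stop("constraint saturated: non-positive factor (F exceeds the density bound)")
  lg <- sum(base::log(factors)) - lgamma(M + 1)
  if (log) lg else exp(lg)
}

#' Stirling approximation to the log map count
#'
#' `F*Np*(1 + ln L - ln x_res - ln F) + sum_{i=1}^{F*Np} ln(1 - (i-1)*D/(L*NI))`.
#'
#' @inheritParams exact_map_count
#' @return Natural log of the number of maps.
#' @export
log_map_count_stirling <- function(params, track, constraint) {
  M <- .n_fields(params)
  stopifnot(M >= 1)
  f <- params$fields_per_cell
  args <- 1 - (seq_len(M) - 1) * constraint$D / (track$L * params$n_int)
  if (any(args <= 0)) stop("log of non-positive argument: constraint saturated")
  M * (1 + base::log(track$L) - base::log(track$x_res) - base::log(f)) +
    sum(base::log(args))
}

#' Number of non-overlapping cell assemblies
#'
#' An assembly of `n` coactive cells satisfying the constraint is built by
#' choosing `n` distinct interneurons and one cell from each interneuron's
#' pool: `N_CA = C(NI, n) * (Np/NI)^n`. Evaluated exactly via log-gamma;
#' the printed Stirling expansion is available via `stirling = TRUE`.
#'
#' @param params A [capacity_params()] with `assembly_size` set.
#' @param stirling Use the Stirling-expanded form.
#' @return Natural log of the number of assemblies.
#' @export
log_assembly_count <- function(params, stirling = FALSE) {
  n <- params$assembly_size
  NI <- params$n_int; Np <- params$n_pyr
  if (is.null(n)) stop("assembly_size not set")
  if (n > NI) stop("assembly_size exceeds interneuron count")
  if (stirling) {
    NI * base::log(NI) - (NI - n) * base::log(NI - n) +
      n * (base::log(Np) - base::log(NI) - base::log(n))
  } else {
    lchoose(NI, n) + n * (base::log(Np) - base::log(NI))
  }
}

#' Number of phase sequences
#'
#' A phase sequence of `m` assemblies with a depleting interneuron pool:
#' `N_PS = prod_{i=1}^{m} C(NI-(i-1)*n, n) * (Np/NI)^(m*n)`, via log-gamma.
#'
#' @param params A [capacity_params()] with `assembly_size` and
#'   `sequence_length` set.
#' @return Natural log of the number of phase sequences.
#' @export
log_sequence_count <- function(params) {
  n <- params$assembly_size; m <- params$sequence_length
  NI <- params$n_int; Np <- params$n_pyr
  if (is.null(n) || is.null(m)) stop("assembly_size and sequence_length required")
  if (m * n > NI) stop("interneuron pool exhausted: m*n > NI")
  sum(lchoose(NI - (seq_len(m) - 1) * n, n)) +
    m * n * (base::log(Np) - base::log(NI))
}

#' Convert a natural log count to a base-10 exponent
#' @param ln_x Natural log of a count.
#' @return `log10` of the count.
#' @export
nat_to_log10 <- function(ln_x) ln_x / base::log(10)

#' Brute-force enumeration of constraint-satisfying maps
#'
#' Exhaustively enumerates all ways to place `round(F*Np)` place fields as
#' distinct (cell, bin) pairs on the circular track and counts those in
#' which no two same-interneuron fields conflict under the chosen exclusion
#' convention. Serves as the independent oracle for [exact_map_count()] on
#' tiny instances (the product formula is exact when exclusion zones of
#' placed fields cannot overlap).
#'
#' @param params A [capacity_params()] (cells assigned to interneurons in
#'   round-robin order, as in [optimal_map()]).
#' @param track A [track_discretization()].
#' @param constraint An [exclusion_constraint()].
#' @param exclusion Convention, as in [verify_map()]; default `"block"`
#'   (the counting convention).
#' @param max_configurations Guard on `C(Np*Nbins, M)`; default 1e7.
#' @return Exact number of distinct maps (integer-valued double).
#' @export
brute_force_map_count <- function(params, track, constraint,
                                  exclusion = c("block", "min_distance"),
                                  max_configurations = 1e7) {
  exclusion <- match.arg(exclusion)
  M <- .n_fields(params)
  Np <- params$n_pyr; nb <- track$n_bins; nd <- constraint$n_d
  n_pairs <- Np * nb
  if (choose(n_pairs, M) > max_configurations)
    stop("instance too large for brute force")
  cell_of <- rep(seq_len(Np), each = nb)
  bin_of <- rep(seq_len(nb) - 1L, times = Np)
  int_of <- ((cell_of - 1) %% params$n_int) + 1L
  conflict <- function(i, j) {
    if (int_of[i] != int_of[j]) return(FALSE)
    if (exclusion == "min_distance")
      .circ_dist(bin_of[i], bin_of[j], nb, track$circular) < nd
    else
      .in_block(bin_of[i], bin_of[j], nd, nb) ||
        .in_block(bin_of[j], bin_of[i], nd, nb)
  }
  if (M == 1) return(n_pairs)
  combos <- utils::combn(n_pairs, M)
  ok <- 0
  for (k in seq_len(ncol(combos))) {
    sel <- combos[, k]
    good <- TRUE
    for (a in seq_len(M - 1)) {
      for (b in (a + 1):M) {
        if (conflict(sel[a], sel[b])) { good <- FALSE; break }
      }
      if (!good) break
    }
    if (good) ok <- ok + 1
  }
  ok
}

#' Capacity summary table
#'
#' Evaluates the density bound and the three log-capacity measures for one
#' parameter set.
#'
#' @param n_pyr,n_int Population sizes.
#' @param fields_per_cell `F`.
#' @param L_m,D_m,x_res_m Track length, exclusion zone and resolution (m).
#' @param assembly_size,sequence_length `n` and `m` (optional).
#' @return Data frame with one row per quantity: `quantity`, `log10_value`
#'   (NA for the density bound, reported in `value`), `value`.
#' @export
capacity_table <- function(n_pyr, n_int, fields_per_cell, L_m, D_m, x_res_m,
                           assembly_size = NULL, sequence_length = NULL) {
  tr <- track_discretization(L_m, x_res_m)
  cn <- exclusion_constraint(D_m, x_res_m)
  pp <- capacity_params(n_pyr, n_int, fields_per_cell, assembly_size,
                        sequence_length)
  rows <- list(
    data.frame(quantity = "density_bound_F_max",
               log10_value = NA_real_,
               value = density_bound(n_int, n_pyr, L_m, D_m)),
    data.frame(quantity = "maps_stirling",
               log10_value = nat_to_log10(log_map_count_stirling(pp, tr, cn)),
               value = NA_real_),
    data.frame(quantity = "maps_exact_form",
               log10_value = nat_to_log10(exact_map_count(pp, tr, cn)),
               value = NA_real_)
  )
  if (!is.null(assembly_size))
    rows <- c(rows, list(data.frame(
      quantity = "assemblies",
      log10_value = nat_to_log10(log_assembly_count(pp)), value = NA_real_)))
  if (!is.null(assembly_size) && !is.null(sequence_length))
    rows <- c(rows, list(data.frame(
      quantity = "phase_sequences",
      log10_value = nat_to_log10(log_sequence_count(pp)), value = NA_real_)))
  do.call(rbind, rows)
}
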