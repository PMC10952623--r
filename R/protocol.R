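## Acquisition-protocol construction: shells x rotations x b-tensor shapes,
## deterministic direction sets, and a pseudo-randomized acquisition order
## that avoids playing the same shell back-to-back (duty-cycle relief).

SHAPE_BDELTA <- c(LTE = 1, PTE = -0.5, STE = 0)

# Spherical Fibonacci lattice on the upper half-sphere (z > 0).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniformly random rotation matrix from a normalized quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# Rotation taking the z axis onto unit vector v (Rodrigues formula).
rotation_z_to <- function(v) {
  v <- unit_vector(v)
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  a <- c(z[2] * v[3] - z[3] * v[2],
         z[3] * v[1] - z[1] * v[3],
         z[1] * v[2] - z[2] * v[1])
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Deterministic, approximately uniform set of encoding directions
#'
#' Spherical Fibonacci lattice on the half-sphere, rotated as a whole by a
#' seeded random rotation so that different seeds give different (but
#' reproducible) sets.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed controlling the global rotation.
#' @return `n x 3` matrix of unit vectors; attribute `rotations` holds a list
#'   of rotation matrices mapping the z axis onto each vector (for
#'   non-axisymmetric use), attribute `min_angle_deg` the pairwise minimum
#'   angle.
#' @export
rotation_set <- function(n, seed = 1L) {
  if (n < 1) stop_validation("n must be >= 1")
  V <- fibonacci_hemisphere(n)
  R <- with_private_seed(seed, random_rotation())
  V <- V %*% t(R)
  min_ang <- if (n >= 2) {
    G <- abs(V %*% t(V))
    diag(G) <- -Inf
    acos(pmin(1, max(G))) * 180 / pi
  } else NA_real_
  rots <- lapply(seq_len(n), function(i) rotation_z_to(V[i, ]))
  structure(V, rotations = rots, min_angle_deg = min_ang)
}

#' Build a multi-shell, multi-shape acquisition scheme
#'
#' For every b-tensor shape and shell, `rotations[i]` orientations from
#' [rotation_set()] are used; the acquisition order is then shuffled with the
#' seed and repaired greedily so that consecutive entries avoid the same
#' shell where possible.
#'
#' @param shells numeric vector of b-values (ms/um^2).
#' @param rotations integer vector, one rotation count per shell.
#' @param shapes character vector of shape labels among `"LTE"`, `"PTE"`,
#'   `"STE"`.
#' @param seed integer seed for directions and ordering.
#' @return object of class `acquisition_scheme`: a list with an `entries`
#'   data frame (index, shape, b, b_delta, the six Voigt components of B in
#'   ms/um^2, rotation index) and the design metadata.
#' @export
build_protocol <- function(shells, rotations, shapes = c("LTE", "PTE"),
                           seed = 1L) {
  if (length(shells) != length(rotations))
    stop_validation("shells and rotations must have equal length")
  shapes <- match.arg(shapes, names(SHAPE_BDELTA), several.ok = TRUE)
  rows <- list()
  for (shape in shapes) {
    bd <- SHAPE_BDELTA[[shape]]
    for (i in seq_along(shells)) {
      # directions are a fixed deterministic set; the seed only controls the
      # acquisition order, so reseeding permutes but never changes the
      # measured multiset
      dirs <- rotation_set(rotations[i], seed = 0L)
      for (k in seq_len(rotations[i])) {
        B <- btensor_from_shape(shells[i], bd, dirs[k, ])
        v <- to_voigt6(B$matrix)
        rows[[length(rows) + 1L]] <- data.frame(
          shape = shape, b = shells[i], b_delta = bd,
          bxx = v[1], byy = v[2], bzz = v[3],
          byz = v[4], bxz = v[5], bxy = v[6],
          rotation = k)
      }
    }
  }
  entries <- do.call(rbind, rows)
  ord <- with_private_seed(seed, sample.int(nrow(entries)))
  entries <- entries[ord, , drop = FALSE]
  entries <- repair_shell_adjacency(entries)
  entries$index <- seq_len(nrow(entries))
  rownames(entries) <- NULL
  entries <- entries[, c("index", "shape", "b", "b_delta",
                         "bxx", "byy", "bzz", "byz", "bxz", "bxy",
                         "rotation")]
  structure(list(entries = entries, shells = shells, rotations = rotations,
                 shapes = shapes, seed = as.integer(seed)),
            class = "acquisition_scheme")
}

# Greedy pass: whenever two consecutive entries share a shell, swap the
# second with the nearest later entry from a different shell (if any).
repair_shell_adjacency <- function(entries) {
  n <- nrow(entries)
  if (n < 3) return(entries)
  for (k in 2:n) {
    if (isTRUE(all.equal(entries$b[k], entries$b[k - 1]))) {
      j <- k
      while (j <= n && isTRUE(all.equal(entries$b[j], entries$b[k - 1]))) j <- j + 1L
      if (j <= n) {
        tmp <- entries[k, ]
        entries[k, ] <- entries[j, ]
        entries[j, ] <- tmp
      }
    }
  }
  entries
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("acquisition scheme: %d volumes, seed %d\n",
              nrow(x$entries), x$seed))
  tab <- table(x$entries$shape, x$entries$b)
  print(tab)
  invisible(x)
}

#' Number of volumes in a scheme
#' @param scheme an `acquisition_scheme`.
#' @return integer count.
#' @export
scheme_length <- function(scheme) nrow(scheme$entries)

# n x 6 matrix of Voigt b-tensor components.
scheme_voigt6 <- function(scheme) {
  as.matrix(scheme$entries[, c("bxx", "byy", "bzz", "byz", "bxz", "bxy")])
}

#' Reconstruct the full 3x3 b-tensor of a scheme entry
#' @param scheme an `acquisition_scheme`.
#' @param i entry index.
#' @return a [btensor()].
#' @export
scheme_btensor <- function(scheme, i) {
  btensor(from_voigt6(as.numeric(scheme_voigt6(scheme)[i, ])))
}

#' Write an acquisition scheme to a tab-separated text file
#'
#' Full-precision, bit-exact round trip with [read_scheme()]. Header lines
#' start with `#` and record the seed and design.
#'
#' @param scheme an `acquisition_scheme`.
#' @param path output file path.
#' @export
write_scheme <- function(scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed %d", scheme$seed),
    sprintf("# shells %s", paste(format(scheme$shells, digits = 17),
                                 collapse = " ")),
    sprintf("# rotations %s", paste(scheme$rotations, collapse = " ")),
    sprintf("# shapes %s", paste(scheme$shapes, collapse = " ")),
    paste(c("# index shape b b_delta bxx byy bzz byz bxz bxy rotation"),
          collapse = " ")), con)
  e <- scheme$entries
  for (k in seq_len(nrow(e))) {
    writeLines(paste(c(e$index[k], e$shape[k],
                       sprintf("%.17g", as.numeric(e[k, 3:10])),
                       e$rotation[k]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an acquisition scheme written by [write_scheme()]
#' @param path path to a scheme file.
#' @return an `acquisition_scheme`.
#' @export
read_scheme <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_hdr <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\b"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    strsplit(sub(paste0("^#\\s*", key, "\\s+"), "", m[1]), "\\s+")[[1]]
  }
  parts <- strsplit(body, "\t")
  entries <- do.call(rbind, lapply(parts, function(p) {
    data.frame(index = as.integer(p[1]), shape = p[2],
               b = as.numeric(p[3]), b_delta = as.numeric(p[4]),
               bxx = as.numeric(p[5]), byy = as.numeric(p[6]),
               bzz = as.numeric(p[7]), byz = as.numeric(p[8]),
               bxz = as.numeric(p[9]), bxy = as.numeric(p[10]),
               rotation = as.integer(p[11]))
  }))
  seed <- get_hdr("seed")
  structure(list(entries = entries,
                 shells = as.numeric(get_hdr("shells")),
                 rotations = as.integer(get_hdr("rotations")),
                 shapes = get_hdr("shapes"),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "acquisition_scheme")
}
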