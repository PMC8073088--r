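#' Build a bidimensional plate-pooling scheme
#'
#' Constructs the two-way (vertical x horizontal) group-testing design used to
#' screen a plate-arrayed population by pooled sequencing. Every sample well
#' belongs to exactly one vertical and one horizontal pool:
#' \itemize{
#'   \item a \emph{vertical} pool collects one plate row across the
#'     \code{pair_size} plates forming that plate's pair
#'     (\code{pair_size * n_cols} samples);
#'   \item a \emph{horizontal} pool collects one plate column across the
#'     \code{group_size} plates forming that plate's group
#'     (\code{group_size * n_rows} samples).
#' }
#' With the default geometry (42 plates of 8 x 12 wells, plate pairs of 2 and
#' plate groups of 6) this yields 168 vertical pools of 24 samples and 84
#' horizontal pools of 48, and any compatible (vertical, horizontal) pool pair
#' intersects in exactly 2 wells, so a pool-level variant decodes to 2
#' candidate lines.
#'
#' @param n_plates number of sample plates (default 42).
#' @param n_rows,n_cols plate geometry (default 8 x 12, a 96-well plate).
#' @param pair_size plates spanned by one vertical pool; must divide
#'   \code{group_size} (default 2).
#' @param group_size plates spanned by one horizontal pool; must divide
#'   \code{n_plates} (default 6).
#' @return An object of class \code{"pooling_scheme"}.
#' @seealso [pools_of()], [decode_pools()], [pool_members()], [pool_manifest()]
#' @examples
#' sc <- build_scheme()
#' sc$n_vpools  # 168
#' decode_pools(sc, pools_of(sc, plate = 0, row = 3, col = 5))
#' @export
build_scheme <- function(n_plates = 42L, n_rows = 8L, n_cols = 12L,
                         pair_size = 2L, group_size = 6L) {
  n_plates <- check_count(n_plates, "n_plates", 1L)
  n_rows <- check_count(n_rows, "n_rows", 1L)
  n_cols <- check_count(n_cols, "n_cols", 1L)
  pair_size <- check_count(pair_size, "pair_size", 1L)
  group_size <- check_count(group_size, "group_size", 1L)
  if (group_size %% pair_size != 0L) {
    stopf("'pair_size' (%d) must divide 'group_size' (%d)", pair_size, group_size)
  }
  if (n_plates %% group_size != 0L) {
    stopf("'group_size' (%d) must divide 'n_plates' (%d)", group_size, n_plates)
  }
  structure(list(
    n_plates = n_plates, n_rows = n_rows, n_cols = n_cols,
    pair_size = pair_size, group_size = group_size,
    n_samples = n_plates * n_rows * n_cols,
    n_vpools = (n_plates %/% pair_size) * n_rows,
    n_hpools = (n_plates %/% group_size) * n_cols,
    vpool_size = pair_size * n_cols,
    hpool_size = group_size * n_rows
  ), class = "pooling_scheme")
}

#' @export
print.pooling_scheme <- function(x, ...) {
  cat(sprintf(
    "Bidimensional pooling scheme: %d plates (%d x %d), %d samples\n",
    x$n_plates, x$n_rows, x$n_cols, x$n_samples
  ))
  cat(sprintf(
    "  %d vertical pools of %d (plate pairs of %d), %d horizontal pools of %d (plate groups of %d)\n",
    x$n_vpools, x$vpool_size, x$pair_size, x$n_hpools, x$hpool_size, x$group_size
  ))
  invisible(x)
}

check_addr <- function(scheme, plate, row, col) {
  n <- max(length(plate), length(row), length(col))
  plate <- rep_len(as.integer(plate), n)
  row <- rep_len(as.integer(row), n)
  col <- rep_len(as.integer(col), n)
  bad <- is.na(plate) | is.na(row) | is.na(col) |
    plate < 0L | plate >= scheme$n_plates |
    row < 0L | row >= scheme$n_rows |
    col < 0L | col >= scheme$n_cols
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf(
      "address out of range for scheme: plate=%s row=%s col=%s",
      plate[i], row[i], col[i]
    )
  }
  list(plate = plate, row = row, col = col)
}

#' Map a sample index to its plate address, and back
#'
#' Samples are indexed 0-based in plate-major, row-major order, so sample 0 is
#' plate 0 well A01 and the last sample is the bottom-right well of the last
#' plate.
#'
#' @param scheme a [build_scheme()] object.
#' @param sample integer vector of 0-based sample indices.
#' @return \code{sample_address()}: data.frame with columns
#'   \code{plate,row,col} (0-based). \code{sample_index()}: integer vector.
#' @export
sample_address <- function(scheme, sample) {
  sample <- as.integer(sample)
  if (any(is.na(sample) | sample < 0L | sample >= scheme$n_samples)) {
    stopf("sample index out of range [0, %d)", scheme$n_samples)
  }
  per_plate <- scheme$n_rows * scheme$n_cols
  data.frame(
    plate = sample %/% per_plate,
    row = (sample %% per_plate) %/% scheme$n_cols,
    col = sample %% scheme$n_cols
  )
}

#' @rdname sample_address
#' @param plate,row,col 0-based address components (vectors are recycled).
#' @export
sample_index <- function(scheme, plate, row, col) {
  a <- check_addr(scheme, plate, row, col)
  a$plate * (scheme$n_rows * scheme$n_cols) + a$row * scheme$n_cols + a$col
}

#' Look up the two pools containing a sample well
#'
#' @param scheme a [build_scheme()] object.
#' @param plate,row,col 0-based address components (vectors are recycled).
#' @return data.frame with integer columns \code{vpool} and \code{hpool}
#'   (0-based pool ids, ordered lexicographically by (plate-pair, row) and
#'   (plate-group, column) respectively).
#' @export
pools_of <- function(scheme, plate, row, col) {
  if (is.list(plate) && missing(row)) {
    row <- plate$row; col <- plate$col; plate <- plate$plate
  }
  a <- check_addr(scheme, plate, row, col)
  data.frame(
    vpool = (a$plate %/% scheme$pair_size) * scheme$n_rows + a$row,
    hpool = (a$plate %/% scheme$group_size) * scheme$n_cols + a$col
  )
}

#' Decode a (vertical, horizontal) pool pair to its candidate wells
#'
#' Returns the intersection of the two pools' member sets. For a compatible
#' pair (the vertical pool's plate pair lies inside the horizontal pool's
#' plate group) this is exactly \code{pair_size} wells sharing a row and a
#' column; for an incompatible pair it is empty.
#'
#' @param scheme a [build_scheme()] object.
#' @param vpool vertical pool id (0-based), or a data.frame as returned by
#'   [pools_of()] in which case \code{hpool} is taken from it.
#' @param hpool horizontal pool id (0-based).
#' @return data.frame of addresses with columns \code{plate,row,col}.
#' @export
decode_pools <- function(scheme, vpool, hpool) {
  if (is.list(vpool) && missing(hpool)) {
    hpool <- vpool$hpool; vpool <- vpool$vpool
  }
  vpool <- check_count(vpool, "vpool")
  hpool <- check_count(hpool, "hpool")
  if (vpool >= scheme$n_vpools) stopf("vpool %d out of range [0, %d)", vpool, scheme$n_vpools)
  if (hpool >= scheme$n_hpools) stopf("hpool %d out of range [0, %d)", hpool, scheme$n_hpools)
  pair <- vpool %/% scheme$n_rows
  row <- vpool %% scheme$n_rows
  group <- hpool %/% scheme$n_cols
  col <- hpool %% scheme$n_cols
  if ((pair * scheme$pair_size) %/% scheme$group_size != group) {
    return(data.frame(plate = integer(), row = integer(), col = integer()))
  }
  data.frame(
    plate = pair * scheme$pair_size + seq_len(scheme$pair_size) - 1L,
    row = row, col = col
  )
}

#' Enumerate the member wells of one pool
#'
#' @param scheme a [build_scheme()] object.
#' @param axis \code{"V"} (vertical) or \code{"H"} (horizontal).
#' @param id 0-based pool id on that axis.
#' @return data.frame of addresses with columns \code{plate,row,col}.
#' @export
pool_members <- function(scheme, axis, id) {
  axis <- match.arg(axis, c("V", "H"))
  id <- check_count(id, "id")
  if (axis == "V") {
    if (id >= scheme$n_vpools) stopf("vpool %d out of range [0, %d)", id, scheme$n_vpools)
    pair <- id %/% scheme$n_rows
    row <- id %% scheme$n_rows
    plates <- pair * scheme$pair_size + seq_len(scheme$pair_size) - 1L
    expand.grid(
      plate = plates, row = row, col = seq_len(scheme$n_cols) - 1L,
      KEEP.OUT.ATTRS = FALSE
    )[, c("plate", "row", "col")]
  } else {
    if (id >= scheme$n_hpools) stopf("hpool %d out of range [0, %d)", id, scheme$n_hpools)
    group <- id %/% scheme$n_cols
    col <- id %% scheme$n_cols
    plates <- group * scheme$group_size + seq_len(scheme$group_size) - 1L
    expand.grid(
      plate = plates, row = seq_len(scheme$n_rows) - 1L, col = col,
      KEEP.OUT.ATTRS = FALSE
    )[, c("plate", "row", "col")]
  }
}

#' Pool id labels used at I/O boundaries
#'
#' Internally pool ids are 0-based integers per axis; manifests, count tables
#' and VCF INFO fields use 1-based labels such as \code{"V001"} and
#' \code{"H084"}.
#'
#' @param axis character vector of \code{"V"}/\code{"H"}.
#' @param id integer vector of 0-based pool ids.
#' @return \code{pool_label()}: character vector. \code{parse_pool_label()}:
#'   data.frame with columns \code{axis}, \code{id}.
#' @export
pool_label <- function(axis, id) {
  sprintf("%s%03d", axis, as.integer(id) + 1L)
}

#' @rdname pool_label
#' @param label character vector of pool labels.
#' @export
parse_pool_label <- function(label) {
  ok <- grepl("^[VH][0-9]+$", label)
  if (!all(ok)) stopf("malformed pool label(s): %s", paste(label[!ok], collapse = ", "))
  data.frame(
    axis = substr(label, 1L, 1L),
    id = as.integer(substr(label, 2L, nchar(label))) - 1L
  )
}

#' Tabulate the full pool manifest of a scheme
#'
#' One row per (pool, member well); the layout a liquid-handling tech or a
#' demultiplexing script consumes.
#'
#' @param scheme a [build_scheme()] object.
#' @return data.frame with columns \code{pool_id}, \code{pool_axis}
#'   (\code{"V"}/\code{"H"}), \code{plate} (1-based) and \code{well}
#'   (e.g. \code{"A01"}).
#' @export
pool_manifest <- function(scheme) {
  rows <- lapply(c("V", "H"), function(axis) {
    n <- if (axis == "V") scheme$n_vpools else scheme$n_hpools
    do.call(rbind, lapply(seq_len(n) - 1L, function(id) {
      m <- pool_members(scheme, axis, id)
      data.frame(
        pool_id = pool_label(axis, id), pool_axis = axis,
        plate = m$plate + 1L, well = well_label(m$row, m$col)
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
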