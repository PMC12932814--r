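#' Factorial design of the crystallisation experiment
#'
#' The Verum experiment crystallises 6 samples per chamber (3 host trees x
#' 2 blending procedures) in 2 chambers (one production batch each), with 4
#' technical replicates per sample, over a number of experimental days.
#' These helpers enumerate that design, derive the mistletoe subspecies from
#' the host tree, and carve out the per-sensitivity-test subsets.
#'
#' @name ccc_design
NULL

.host_levels <- c("apple", "oak", "pine")
.blending_levels <- c("machine", "hand")
.batch_levels <- c("2109", "2204")
.subspecies_levels <- c("VAA", "VAAu")

# chamber -> batch is a fixed property of the experiment
.chamber_batch <- c(`1` = "2109", `2` = "2204")

#' Chamber layout: the physical allocation positions
#'
#' A crystallisation chamber holds 43 Petri-dish positions arranged in two
#' concentric rings; only a subset (by default the first 24) is used for the
#' randomised samples.
#'
#' @param n_inner,n_outer Number of positions in the inner and outer ring;
#'   they must sum to 43 for the standard chamber.
#' @param used Integer vector of position indices actually assigned to
#'   samples. Defaults to `1:24` (6 blocks of 4).
#' @return An object of class `ccc_chamber_layout`: a data frame with
#'   columns `position` and `ring`, plus a `used` attribute.
#' @export
chamber_layout <- function(n_inner = 18L, n_outer = 25L, used = 1:24) {
  n_inner <- as.integer(n_inner); n_outer <- as.integer(n_outer)
  if (n_inner < 1L || n_outer < 1L) stop("ring sizes must be positive")
  n <- n_inner + n_outer
  used <- sort(unique(as.integer(used)))
  if (any(used < 1L | used > n)) stop("'used' positions must lie in 1..", n)
  layout <- data.frame(
    position = seq_len(n),
    ring = rep(c("inner", "outer"), c(n_inner, n_outer)),
    stringsAsFactors = FALSE
  )
  attr(layout, "used") <- used
  class(layout) <- c("ccc_chamber_layout", "data.frame")
  layout
}

#' @export
print.ccc_chamber_layout <- function(x, ...) {
  cat(sprintf("Chamber layout: %d positions (%d inner, %d outer), %d used\n",
              nrow(x), sum(x$ring == "inner"), sum(x$ring == "outer"),
              length(attr(x, "used"))))
  invisible(x)
}

#' Derive the mistletoe subspecies from the host tree
#'
#' *Viscum album* subsp. *album* (VAA) grows on deciduous hosts (apple,
#' oak); subsp. *austriacum* (VAAu) is bound to pine.
#'
#' @param host_tree Character vector with values in
#'   `c("apple", "oak", "pine")`.
#' @return Character vector of `"VAA"` / `"VAAu"`.
#' @export
derive_subspecies <- function(host_tree) {
  host_tree <- as.character(host_tree)
  bad <- setdiff(unique(host_tree), .host_levels)
  if (length(bad)) {
    stop("unknown host tree(s): ", paste(bad, collapse = ", "))
  }
  ifelse(host_tree == "pine", "VAAu", "VAA")
}

# the 6 samples of one chamber, in canonical order
.chamber_samples <- function() {
  expand.grid(blending = .blending_levels, host_tree = .host_levels,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
}

#' Default counterbalanced rotation (cyclic Latin square)
#'
#' @param n Side length (6 samples, 6 blocks).
#' @return An `n x n` integer matrix, rows = days, columns = samples,
#'   entries = block index; every row and column is a permutation.
#' @seealso [build_rotation()] for a seeded random Latin square.
#' @export
default_rotation <- function(n = 6L) {
  m <- outer(seq_len(n), seq_len(n), function(d, s) ((d + s - 2L) %% n) + 1L)
  structure(m, class = c("ccc_rotation", class(m)))
}

.check_rotation <- function(rotation, n_days, n_samples = 6L) {
  rotation <- unclass(rotation)
  if (!is.matrix(rotation) || ncol(rotation) != n_samples) {
    stop("rotation must be a matrix with ", n_samples, " sample columns")
  }
  if (nrow(rotation) < n_days) {
    stop("rotation covers ", nrow(rotation), " days but ", n_days,
         " are requested")
  }
  for (d in seq_len(n_days)) {
    if (!setequal(rotation[d, ], seq_len(n_samples))) {
      stop("rotation row ", d, " is not a bijection between samples and blocks")
    }
  }
  invisible(rotation)
}

# default block -> positions map when no searched scheme is supplied:
# contiguous groups of 4 among the layout's used positions
.default_blocks <- function(layout) {
  used <- attr(layout, "used")
  if (length(used) != 24L) {
    stop("layout must have 24 used positions to form 6 blocks of 4")
  }
  split(used, rep(1:6, each = 4L))
}

#' Enumerate the full Verum design
#'
#' Builds one record per fingerprint: `n_days` days x 2 chambers x 6
#' samples x 4 replicates. Sample-to-block assignment follows the rotation
#' (a Latin square over days), and block-to-position assignment follows the
#' per-chamber randomisation schemes.
#'
#' @param n_days Number of experimental days (6 for the full design).
#' @param layout A [chamber_layout()].
#' @param rotation Day x sample block assignment; see [default_rotation()].
#' @param schemes Optional list of two [select_scheme()] results (one per
#'   chamber); when `NULL`, blocks map to contiguous groups of 4 used
#'   positions.
#' @return A `ccc_design` data frame with columns `plate_id`, `day`,
#'   `batch`, `chamber`, `host_tree`, `blending`, `subspecies`,
#'   `sample_code`, `block`, `allocation`, `replicate`.
#' @examples
#' d <- build_verum_design()
#' nrow(d)            # 288
#' table(d$day)       # 48 per day
#' @export
build_verum_design <- function(n_days = 6L, layout = chamber_layout(),
                               rotation = default_rotation(),
                               schemes = NULL) {
  n_days <- as.integer(n_days)
  if (n_days < 0L) stop("n_days must be >= 0")
  cols <- c("plate_id", "day", "batch", "chamber", "host_tree", "blending",
            "subspecies", "sample_code", "block", "allocation", "replicate")
  if (n_days == 0L) {
    out <- data.frame(plate_id = character(), day = integer(),
                      batch = character(), chamber = integer(),
                      host_tree = character(), blending = character(),
                      subspecies = character(), sample_code = character(),
                      block = integer(), allocation = integer(),
                      replicate = integer(), stringsAsFactors = FALSE)
    class(out) <- c("ccc_design", "data.frame")
    return(out)
  }
  .check_rotation(rotation, n_days)
  samples <- .chamber_samples()
  if (is.null(schemes)) {
    blocks <- .default_blocks(layout)
    schemes <- list(list(blocks = blocks), list(blocks = blocks))
  }
  if (length(schemes) != 2L) stop("schemes must be a list of 2 (one per chamber)")
  codes <- list(`1` = LETTERS[1:6], `2` = LETTERS[7:12])

  rows <- vector("list", n_days * 2L * 6L)
  k <- 0L
  for (day in seq_len(n_days)) {
    for (chamber in 1:2) {
      blocks <- schemes[[chamber]]$blocks
      for (s in 1:6) {
        block <- unclass(rotation)[day, s]
        pos <- blocks[[block]]
        if (length(pos) != 4L) stop("block ", block, " does not hold 4 positions")
        k <- k + 1L
        rows[[k]] <- data.frame(
          day = day,
          batch = unname(.chamber_batch[as.character(chamber)]),
          chamber = chamber,
          host_tree = samples$host_tree[s],
          blending = samples$blending[s],
          sample_code = codes[[chamber]][s],
          block = as.integer(block),
          allocation = as.integer(pos),
          replicate = 1:4,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$subspecies <- derive_subspecies(out$host_tree)
  out$plate_id <- sprintf("d%dc%d%s r%d", out$day, out$chamber,
                          out$sample_code, out$replicate)
  out$plate_id <- gsub(" ", "", out$plate_id)
  out <- out[, cols]
  # allocation must be unique within (day, chamber)
  dup <- tapply(out$allocation, paste(out$day, out$chamber),
                function(a) anyDuplicated(a) > 0L)
  if (any(dup)) stop("allocation collision within a (day, chamber) cell")
  rownames(out) <- NULL
  class(out) <- c("ccc_design", "data.frame")
  out
}

#' Subset the design for one of the three sensitivity tests
#'
#' @param design A `ccc_design` (full Verum design).
#' @param test_id One of `"subspecies"` (all 288 plates; 4th factor is the
#'   subspecies, pooling apple+oak against pine), `"deciduous"` (the 192
#'   VAA plates only; 4th factor is the deciduous host tree), or
#'   `"blending"` (all plates; 4th factor is the blending procedure).
#' @return A list with elements `design` (the subset), `factors` (the four
#'   ANOVA factors), `focus` (the factor of interest) and `contrast`
#'   (the two levels compared for the effect size).
#' @export
sensitivity_subset <- function(design,
                               test_id = c("subspecies", "deciduous", "blending")) {
  test_id <- match.arg(test_id)
  stopifnot(is.data.frame(design))
  sub <- switch(test_id,
    subspecies = list(
      design = design,
      factors = c("day", "batch", "blending", "subspecies"),
      focus = "subspecies",
      contrast = c("VAA", "VAAu")
    ),
    deciduous = list(
      design = design[design$subspecies == "VAA", , drop = FALSE],
      factors = c("day", "batch", "blending", "host_tree"),
      focus = "host_tree",
      contrast = c("apple", "oak")
    ),
    blending = list(
      design = design,
      factors = c("day", "batch", "host_tree", "blending"),
      focus = "blending",
      contrast = c("machine", "hand")
    )
  )
  rownames(sub$design) <- NULL
  sub$test_id <- test_id
  sub
}

#' Read / write a design table as CSV
#'
#' Columns: plate_id, day, batch, chamber, host_tree, blending, subspecies,
#' block, allocation, replicate (enum values lower-case, header mandatory).
#'
#' @param design A `ccc_design`.
#' @param path File path.
#' @return `read_design_csv` returns a `ccc_design`; `write_design_csv`
#'   returns `path` invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(batch = "character"))
  need <- c("plate_id", "day", "batch", "host_tree", "blending",
            "subspecies", "block", "allocation", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("design CSV lacks columns: ", paste(miss, collapse = ", "))
  chk <- derive_subspecies(d$host_tree)
  if (!identical(chk, d$subspecies)) {
    stop("subspecies column inconsistent with host_tree")
  }
  class(d) <- c("ccc_design", "data.frame")
  d
}
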