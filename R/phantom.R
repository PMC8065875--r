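## Synthetic multi-tissue head phantom and labelled-atlas I/O.
##
## The generator produces a nested-ellipsoid head: skin and adipose shells,
## three-layer skull (outer table, diploe, inner table), muscle, meninges,
## subarachnoid CSF, a cortical grey-matter ribbon, white-matter interior
## with ventricles, periventricular white-matter-hyperintensity caps, one
## basal-ganglia stroke lesion, subcortical grey-matter blobs, tubular
## vessels crossing the brain surface, eyes and an inferior neck block with
## a bone column. Geometry is parameterised in absolute mm, so the same head
## can be sampled at any grid spacing.

#' Tissue classes of the synthetic head phantom
#'
#' Sixteen regions of interest: CSF, normal-appearing white matter (NAWM),
#' white matter hyperintensities (WMH), stroke lesion, cortical and
#' subcortical grey matter, meninges, muscle and cartilage, mandible and
#' vertebrae, skull diploe, skull inner and outer tables, blood vessels,
#' skin and connective tissue, adipose tissue, and eyes.
#'
#' @return data.frame with columns \code{class_id} and \code{name}.
#' @export
phantomClassTable <- function() {
  data.frame(
    class_id = 1:16,
    name = c("csf", "nawm", "wmh", "stroke", "cortical_gm", "subcortical_gm",
             "meninges", "muscle", "mandible_vertebrae", "skull_diploe",
             "skull_inner_table", "skull_outer_table", "vessels", "skin",
             "adipose", "eyes"),
    stringsAsFactors = FALSE)
}

BRAIN_CLASSES <- c("nawm", "wmh", "stroke", "cortical_gm", "subcortical_gm")

#' Specification of the synthetic head phantom
#'
#' @param dim integer(3) grid size in voxels.
#' @param spacingMM numeric(3) voxel size in mm (the full-scale reference object uses
#'   0.5 mm isotropic; the demo default is 1 mm).
#' @param classes integer vector of class IDs to include (default all 16).
#' @param headSemiAxesMM outer head ellipsoid semi-axes in mm; default fills
#'   92\% of the smallest half-FOV with mild anisotropy.
#' @param jitterMM magnitude of the seeded random jitter applied to internal
#'   structure centres, mm.
#' @return a list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(dim = c(96L, 96L, 96L), spacingMM = c(1, 1, 1),
                        classes = 1:16, headSemiAxesMM = NULL,
                        jitterMM = 1) {
  dim <- as.integer(rep(dim, length.out = 3))
  spacingMM <- rep(spacingMM, length.out = 3)
  if (is.null(headSemiAxesMM)) {
    r <- 0.92 * min(dim * spacingMM) / 2
    headSemiAxesMM <- r * c(0.95, 0.88, 1.0)
  }
  structure(list(dim = dim, spacingMM = spacingMM, classes = sort(classes),
                 headSemiAxesMM = headSemiAxesMM, jitterMM = jitterMM),
            class = "PhantomSpec")
}

## ellipsoid membership helper on world-coordinate arrays
.ellip <- function(X, Y, Z, centre, semi) {
  ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
    ((Z - centre[3]) / semi[3])^2 <= 1
}

## squared distance from the line through p with unit direction d
.lineDist2 <- function(X, Y, Z, p, d) {
  wx <- X - p[1]; wy <- Y - p[2]; wz <- Z - p[3]
  t <- wx * d[1] + wy * d[2] + wz * d[3]
  (wx - t * d[1])^2 + (wy - t * d[2])^2 + (wz - t * d[3])^2
}

#' Build the synthetic labelled head phantom
#'
#' Deterministically (given \code{seed}) constructs the nested-ellipsoid
#' head described in \code{\link{phantomSpec}}. Every requested class is
#' checked to be present; a grid too small to host a class raises an error
#' naming it.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed integer seed controlling the structure-centre jitter.
#' @return A \linkS4class{LabelVolume}.
#' @export
buildSyntheticHead <- function(spec = phantomSpec(), seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  jit <- function(n = 3) stats::runif(n, -spec$jitterMM, spec$jitterMM)

  d <- spec$dim; sp <- spec$spacingMM
  A <- gridAffine(d, sp)
  xs <- axisWorld(d, A, 1); ys <- axisWorld(d, A, 2); zs <- axisWorld(d, A, 3)
  X <- array(xs, d)
  Y <- aperm(array(ys, d[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(zs, d[c(3, 1, 2)]), c(2, 3, 1))

  ax <- spec$headSemiAxesMM
  rho <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)

  lab <- array(0L, d)
  shell <- function(lo, hi) rho > lo & rho <= hi
  ## outside-in concentric shells (fractions of the head radius)
  lab[shell(0.94, 1.00)] <- 14L   # skin / connective tissue
  lab[shell(0.88, 0.94)] <- 15L   # adipose
  lab[shell(0.80, 0.88)] <- 8L    # muscle and cartilage
  lab[shell(0.76, 0.80)] <- 12L   # skull outer table
  lab[shell(0.71, 0.76)] <- 10L   # skull diploe
  lab[shell(0.66, 0.71)] <- 11L   # skull inner table
  lab[shell(0.625, 0.66)] <- 7L   # meninges
  lab[shell(0.585, 0.625)] <- 1L  # subarachnoid CSF
  lab[shell(0.50, 0.585)] <- 5L   # cortical grey-matter ribbon
  lab[rho <= 0.50] <- 2L          # white-matter interior

  ## neck: inferior cylinder of muscle with a bone column
  neck <- Z < -0.80 * ax[3] & (X^2 + Y^2) <= (0.55 * ax[1])^2 & lab == 0L
  lab[neck] <- 8L
  bone <- Z < -0.80 * ax[3] & (X^2 + Y^2) <= (0.22 * ax[1])^2
  lab[bone & (neck | lab == 8L)] <- 9L  # mandible and vertebrae

  wm <- lab == 2L
  s <- min(ax) # structure scale
  ## lateral ventricles: two elongated ellipsoids either side of midline
  vc <- c(0, -0.04 * s, 0.08 * s) + jit()
  off <- c(0.14 * s, 0, 0)
  vsemi <- c(0.07, 0.22, 0.10) * s
  vent <- .ellip(X, Y, Z, vc + off, vsemi) | .ellip(X, Y, Z, vc - off, vsemi)
  lab[vent & wm] <- 1L
  ## periventricular WMH caps: shell around the ventricles, within WM
  wcap <- (.ellip(X, Y, Z, vc + off, vsemi * 1.45) |
           .ellip(X, Y, Z, vc - off, vsemi * 1.45)) & !vent
  lab[wcap & lab == 2L] <- 3L
  ## subcortical grey matter: thalamus-like blobs lateral to the ventricles
  tc <- c(0.26 * s, -0.02 * s, 0) + jit()
  tsemi <- c(0.09, 0.13, 0.10) * s
  thal <- .ellip(X, Y, Z, tc, tsemi) | .ellip(X, Y, Z, tc * c(-1, 1, 1), tsemi)
  lab[thal & lab %in% c(2L, 3L)] <- 6L
  ## one basal-ganglia stroke lesion
  sc <- c(0.30 * s, 0.16 * s, -0.06 * s) + jit()
  stro <- .ellip(X, Y, Z, sc, c(0.08, 0.08, 0.07) * s)
  lab[stro & lab %in% c(2L, 3L, 6L)] <- 4L

  ## tubular vessels crossing the brain surface: thin tubes confined to the
  ## cortical crossing zone (meninges/CSF/GM and outer white matter) so that
  ## each host class loses well under 1% of its volume to the carving
  vrad2 <- 1.3^2
  dirs <- rbind(c(0.1, 0.25, 0.96), c(0.9, 0.2, 0.38), c(-0.5, 0.8, 0.33))
  pts <- rbind(c(0, -0.1 * s, 0), c(0.05 * s, 0.15 * s, 0.1 * s),
               c(-0.1 * s, 0, -0.05 * s))
  for (v in 1:3) {
    dv <- dirs[v, ] + stats::runif(3, -0.05, 0.05)
    dv <- dv / sqrt(sum(dv^2))
    tube <- .lineDist2(X, Y, Z, pts[v, ] + jit(), dv) <= vrad2
    lab[tube & rho >= 0.42 & rho <= 0.71] <- 13L
  }

  ## eyes: two anterior globes
  ec <- c(0.32 * ax[1], 0.80 * ax[2], 0.05 * ax[3])
  eye <- .ellip(X, Y, Z, ec, rep(5.5, 3)) |
         .ellip(X, Y, Z, ec * c(-1, 1, 1), rep(5.5, 3))
  lab[eye] <- 16L

  ## restrict to the requested classes: drop others back to their host shell
  keep <- spec$classes
  tab <- phantomClassTable()
  if (!(13L %in% keep)) {
    ## vessels removed first: each carved voxel reverts to its host shell,
    ## which the generic removal below may then drop in turn
    idx <- which(lab == 13L)
    lab[idx] <- ifelse(rho[idx] <= 0.50, 2L,
                ifelse(rho[idx] <= 0.585, 5L,
                ifelse(rho[idx] <= 0.625, 1L,
                ifelse(rho[idx] <= 0.66, 7L, 11L))))
  }
  host <- c(`3` = 2L, `4` = 2L, `6` = 2L, `16` = 15L)
  for (id in setdiff(setdiff(1:16, keep), 13L)) {
    repl <- if (as.character(id) %in% names(host)) host[[as.character(id)]] else 0L
    if (!(repl %in% c(0L, keep))) repl <- 0L
    lab[lab == id] <- repl
  }

  present <- unique(as.vector(lab))
  missing <- setdiff(keep, present)
  if (length(missing))
    stop("grid too small to host class(es): ",
         paste(tab$name[match(missing, tab$class_id)], collapse = ", "))

  cn <- stats::setNames(tab$name[match(keep, tab$class_id)], as.character(keep))
  LabelVolume(lab, spacing = sp, affine = A, classNames = cn)
}

## ---------------------------------------------------------------------------
## NIfTI I/O
## ---------------------------------------------------------------------------

#' Read a labelled atlas volume from NIfTI
#'
#' Permits substituting an external comprehensively-labelled head atlas for
#' the synthetic phantom. The file must contain a single integer-valued 3D
#' volume; IDs absent from \code{classMap} raise an error listing them.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param classMap named character vector, class IDs (as names) to tissue
#'   names.
#' @return A \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(path, classMap) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L) stop("expected a single 3D volume")
  if (max(abs(arr - round(arr))) > 1e-6) stop("non-integer label data")
  arr <- array(as.integer(round(arr)), dim(arr))
  ids <- setdiff(unique(as.vector(arr)), 0L)
  unknown <- setdiff(as.character(ids), names(classMap))
  if (length(unknown))
    stop("label IDs not in class map: ", paste(unknown, collapse = ", "))
  A <- unclass(RNifti::xform(img))
  sp <- sqrt(colSums(A[1:3, 1:3]^2))   # spacing from the affine columns
  LabelVolume(arr, spacing = sp, affine = A, classNames = classMap)
}

#' Write a LabelVolume to NIfTI
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@labels, datatype = "uint16")
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Tissue parameter table and parameter assignment
## ---------------------------------------------------------------------------

#' Validate a tissue parameter table
#'
#' The table carries, per tissue class, the equilibrium signal S0, the
#' pre-contrast relaxation times T10 and T2*0 (s), the ground-truth plasma
#' volume fraction vP and permeability-surface area product PS (per
#' minute), and how the class enhances: \code{"patlak"} (brain tissue and
#' vessels), \code{"extracerebral_curve"} (non-brain enhancing tissue) or
#' \code{"none"}. Vessels carry \code{NA} vP in the table; it is filled with
#' 1 - Hct at assignment time, and their PS is 0.
#'
#' @param df data.frame with columns \code{class_id}, \code{name},
#'   \code{S0}, \code{T10_s}, \code{T2star0_s}, \code{vP}, \code{PS_per_min},
#'   \code{enhancement_mode}, \code{curve_params} (JSON string).
#' @return the validated data.frame (invisibly classed
#'   \code{"TissueParameterTable"}).
#' @export
tissueParameterTable <- function(df) {
  need <- c("class_id", "name", "S0", "T10_s", "T2star0_s", "vP",
            "PS_per_min", "enhancement_mode", "curve_params")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$T10_s <= 0)) stop("T10 must be positive")
  if (any(df$T2star0_s <= 0)) stop("T2*0 must be positive")
  vp <- df$vP[!is.na(df$vP)]
  if (any(vp < 0 | vp > 1)) stop("vP must lie in [0, 1]")
  if (any(df$PS_per_min < 0, na.rm = TRUE)) stop("ground-truth PS must be >= 0")
  if (!all(df$enhancement_mode %in% c("patlak", "extracerebral_curve", "none")))
    stop("unknown enhancement_mode")
  bad <- df$name %in% BRAIN_CLASSES & df$enhancement_mode != "patlak"
  if (any(bad))
    stop("brain classes must use the patlak enhancement mode: ",
         paste(df$name[bad], collapse = ", "))
  ves <- df$name == "vessels"
  if (any(ves) && any(df$PS_per_min[ves] != 0)) stop("vessels must have PS = 0")
  class(df) <- c("TissueParameterTable", "data.frame")
  invisible(df)
}

#' Assign voxelwise tissue parameters from a label volume
#'
#' Maps the per-class table onto the grid, yielding piecewise-constant
#' parameter volumes. Vessel vP is set to 1 - Hct; background voxels get
#' S0 = 0 and PS = 0.
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @param table a \code{\link{tissueParameterTable}}.
#' @param hct haematocrit used for the vessel plasma volume fraction.
#' @return list of 3D arrays \code{S0}, \code{T10}, \code{T2star0},
#'   \code{vP}, \code{PS}, plus the per-class lookup used
#'   (attribute \code{"classLookup"}).
#' @export
assignParameters <- function(vol, table, hct = 0.45) {
  ids <- setdiff(sort(unique(as.vector(vol@labels))), 0L)
  missing <- setdiff(ids, table$class_id)
  if (length(missing)) {
    nm <- vol@classNames[as.character(missing)]
    stop("no parameter row for class(es): ",
         paste(ifelse(is.na(nm), missing, nm), collapse = ", "))
  }
  tab <- as.data.frame(table)
  tab$vP[tab$name == "vessels"] <- 1 - hct
  tab$vP[is.na(tab$vP)] <- 0
  tab$PS_per_min[is.na(tab$PS_per_min)] <- 0

  ## lookup vectors indexed by label + 1 (0 = background)
  maxId <- max(tab$class_id)
  mk <- function(col, bg) {
    v <- rep(bg, maxId + 1)
    v[tab$class_id + 1] <- tab[[col]]
    v
  }
  lk <- list(S0 = mk("S0", 0), T10 = mk("T10_s", 1), T2star0 = mk("T2star0_s", 1),
             vP = mk("vP", 0), PS = mk("PS_per_min", 0))
  idx <- as.vector(vol@labels) + 1L
  out <- lapply(lk, function(v) array(v[idx], dim(vol@labels)))
  attr(out, "classLookup") <- tab
  attr(out, "hct") <- hct
  out
}

#' Read a tissue parameter table from CSV
#' @param path CSV file with the columns of \code{\link{tissueParameterTable}}.
#' @return a validated \code{TissueParameterTable}.
#' @export
readTissueTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tissueParameterTable(df)
}
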