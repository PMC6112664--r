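#' Persist a k-space set in an HDF5 container
#'
#' Layout: complex data are stored as paired real/imaginary datasets
#' (`/kspace/re`, `/kspace/im`, dims ky x kx x coil x echo x group x frame;
#' `/navigators/re`, `/navigators/im`), the acquisition parameters and
#' sequence plan as JSON strings (`/meta/params`, `/meta/plan`), plus
#' `/meta/type` and `/meta/slice_map`.
#'
#' @param ks a `kspace_set`.
#' @param path HDF5 file path (overwritten).
#' @return the path, invisibly.
#' @export
save_kspace_set <- function(ks, path) {
  stopifnot(inherits(ks, "kspace_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "kspace")
  rhdf5::h5write(Re(ks$kspace), path, "kspace/re")
  rhdf5::h5write(Im(ks$kspace), path, "kspace/im")
  if (!is.null(ks$navigators)) {
    rhdf5::h5createGroup(path, "navigators")
    rhdf5::h5write(Re(ks$navigators), path, "navigators/re")
    rhdf5::h5write(Im(ks$navigators), path, "navigators/im")
  }
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(as.character(jsonlite::toJSON(unclass(ks$params),
                                               auto_unbox = TRUE, digits = NA)),
                 path, "meta/params")
  rhdf5::h5write(as.character(jsonlite::toJSON(unclass(ks$plan),
                                               auto_unbox = TRUE, digits = NA)),
                 path, "meta/plan")
  rhdf5::h5write(ks$type, path, "meta/type")
  rhdf5::h5write(ks$slice_map, path, "meta/slice_map")
  rhdf5::H5close()
  invisible(path)
}

#' @rdname save_kspace_set
#' @export
load_kspace_set <- function(path) {
  ks <- rhdf5::h5read(path, "kspace")
  kspace <- ks$re + 1i * ks$im
  navs <- NULL
  if ("navigators" %in% rhdf5::h5ls(path)$name) {
    nv <- rhdf5::h5read(path, "navigators")
    navs <- nv$re + 1i * nv$im
  }
  params <- jsonlite::fromJSON(rhdf5::h5read(path, "meta/params"))
  params$ghost_phase <- as.numeric(params$ghost_phase)
  class(params) <- "acquisition_params"
  plan_l <- jsonlite::fromJSON(rhdf5::h5read(path, "meta/plan"),
                               simplifyMatrix = TRUE)
  plan_l$segment_lines <- lapply(seq_len(nrow(plan_l$segment_lines)),
                                 function(i) plan_l$segment_lines[i, ])
  if (is.vector(plan_l$te_effective)) {
    plan_l$te_effective <- matrix(plan_l$te_effective, nrow = plan_l$n_segments)
  }
  class(plan_l) <- "sequence_plan"
  type <- as.character(rhdf5::h5read(path, "meta/type"))
  slice_map <- rhdf5::h5read(path, "meta/slice_map")
  rhdf5::H5close()
  new_kspace_set(kspace, navs, plan_l, params, type, slice_map)
}

#' Persist a slice kernel under /kernels of an HDF5 file
#'
#' @param kernel a `slice_kernel`.
#' @param path HDF5 file (created if absent).
#' @return the path, invisibly.
#' @export
save_slice_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "slice_kernel"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "kernels")
  for (nm in names(kernel$kernels)) {
    g <- paste0("kernels/echo", nm)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(Re(kernel$kernels[[nm]]), path, paste0(g, "/re"))
    rhdf5::h5write(Im(kernel$kernels[[nm]]), path, paste0(g, "/im"))
  }
  meta <- kernel[c("kernel_size", "lambda", "algorithm", "acs_policy",
                   "mb", "f", "n_groups", "n_coils", "method")]
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                               digits = NA)),
                 path, "kernels/meta")
  rhdf5::h5write(kernel$residual, path, "kernels/residual")
  rhdf5::H5close()
  invisible(path)
}

#' @rdname save_slice_kernel
#' @export
load_slice_kernel <- function(path) {
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "kernels/meta"))
  ls <- rhdf5::h5ls(path)
  echo_groups <- grep("^echo", ls$name[ls$group == "/kernels"], value = TRUE)
  kernels <- list()
  for (g in sort(echo_groups)) {
    x <- rhdf5::h5read(path, paste0("kernels/", g))
    kernels[[sub("^echo", "", g)]] <- x$re + 1i * x$im
  }
  residual <- rhdf5::h5read(path, "kernels/residual")
  rhdf5::H5close()
  structure(c(list(kernels = kernels, residual = residual), meta),
            class = "slice_kernel")
}

#' Pipeline configuration
#'
#' `default_config()` returns the full default configuration; JSON config
#' files (the "structured text config" dialect) may override any subset.
#' `read_config()` merges a file over the defaults and rejects unknown keys
#' by name; `validate_config()` checks required keys.
#'
#' @param path JSON file.
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "smsepi_out",
    phantom = list(grid_shape = c(4L, 48L, 48L), vessel = TRUE),
    coils = list(n_coils = 6L, smoothness = NULL),
    acquisition = list(fa = 90, tr = 261, te_list = c(9, 21.5, 34),
                       n_segments = 4L, fov_shift_factor = 4L, mb = 4L,
                       noise_sd = 0.02, ghost_phase = c(0, 0), ets_us = 150),
    acs = list(tr = 1500, noise_sd = 0.002),
    plan = list(n_frames = 8L, dead_time = 261),
    bolus = list(enabled = TRUE, t0 = 3, alpha = 3, beta = 1.5,
                 peak_conc = 5, r1 = 4, r2s = 5,
                 recirculation_fraction = 0.15, steady_level = 0.5),
    recon = list(method = 1L, algorithm = "sg", policy = "acs111",
                 kernel_size = c(5L, 5L), lambda = 1e-4,
                 acs_grid = c(64L, 64L), nav_correct = TRUE),
    qa = list(g_replicas = 30L, bin_width = 5),
    relax = list(t2s_min = 0.1, t2s_max = 2000),
    log_level = "info"
  )
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  def <- default_config()
  unknown <- character(0)
  merge1 <- function(d, u, prefix = "") {
    for (k in names(u)) {
      if (!k %in% names(d)) {
        unknown <<- c(unknown, paste0(prefix, k))
      } else if (is.list(d[[k]]) && is.list(u[[k]])) {
        d[[k]] <- merge1(d[[k]], u[[k]], paste0(prefix, k, "."))
      } else {
        d[[k]] <- u[[k]]
      }
    }
    d
  }
  cfg <- merge1(def, user)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  validate_config(cfg)
}

#' @rdname default_config
#' @param config configuration list.
#' @export
validate_config <- function(config) {
  required <- names(default_config())
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("missing required config keys: ", paste(missing, collapse = ", "))
  }
  stopifnot(length(config$phantom$grid_shape) == 3)
  config
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), f)
  unname(tools::md5sum(f))
}

write_manifest <- function(dir, config, artifacts) {
  sums <- tools::md5sum(artifacts[file.exists(artifacts)])
  manifest <- list(config = config, config_hash = config_hash(config),
                   seed = config$seed,
                   artifacts = as.list(sums))
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(p)
}
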