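#' Read and write session CSV files
#'
#' Sessions are stored as plain CSV with columns
#' `t,ax,ay,az,gx,gy,gz,activity` (time in s, acceleration in g, angular
#' rate in deg/s) preceded by `#` comment lines documenting units and the
#' sampling rate. Round-trips preserve values to better than 1e-9.
#'
#' @param trace a labelled [imu_trace()].
#' @param path file path.
#' @return `write_session()` returns the path invisibly; `read_session()`
#'   returns an [imu_trace()].
#' @export
write_session <- function(trace, path) {
  if (!inherits(trace, "imu_trace")) stop("trace must be an imu_trace")
  if (is.null(trace$labels)) stop("trace must be labelled for session files")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# actiflow session v1",
               "# units: t s, ax/ay/az g, gx/gy/gz deg/s",
               sprintf("# fs: %.10g Hz", trace$fs)), con)
  d <- as.data.frame(trace)
  d[1:7] <- lapply(d[1:7], function(x) sprintf("%.12g", x))
  utils::write.table(d, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 10)
  fs_line <- grep("^# fs:", header, value = TRUE)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "activity")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  bad <- integer(0)
  for (cn in num) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- union(bad, which(!is.finite(v)))
    d[[cn]] <- v
  }
  if (length(bad))
    stop("malformed row(s): ", paste(utils::head(sort(bad), 5), collapse = ", "))
  if (any(diff(d$t) <= 0)) {
    i <- which(diff(d$t) <= 0)[1]
    stop("non-monotone time at row ", i + 1)
  }
  fs <- if (length(fs_line)) as.numeric(sub("^# fs:\\s*([0-9.eE+-]+).*$", "\\1",
                                            fs_line[1]))
        else 1 / stats::median(diff(d$t))
  imu_trace(d$t, d$ax, d$ay, d$az, d$gx, d$gy, d$gz, fs = fs,
            labels = d$activity)
}

#' Write and read window feature matrices as CSV
#'
#' One row per window: the 98 feature columns (catalogue order), plus
#' `label` (intensity class 0/1/2) and `subject_id`.
#'
#' @param fm a feature matrix list as from [feature_matrix()].
#' @param path file path.
#' @return `write_feature_csv()` returns the path invisibly;
#'   `read_feature_csv()` returns a [feature_matrix()]-shaped list.
#' @export
write_feature_csv <- function(fm, path) {
  d <- as.data.frame(fm$X)
  d$label <- fm$label
  d$subject_id <- fm$subject
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("label", "subject_id") %in% names(d)))
    stop("feature CSV must contain label and subject_id columns")
  feats <- setdiff(names(d), c("label", "subject_id"))
  list(X = as.matrix(d[feats]), label = as.integer(d$label),
       subject = as.character(d$subject_id))
}

#' Run configuration
#'
#' Defaults mirror the deployed system: 25 Hz sampling, 3-s windows,
#' 0.15 Hz DC cutoff, wrapper termination 5 with 5-fold CV, tree + LDA
#' nodes, therapy profile 2.
#'
#' @param path optional YAML file whose entries override the defaults.
#' @return A nested list of class `run_config` with a `hash` stamp.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(
    sampling = list(fs = 25, window_s = 3, cutoff_hz = 0.15),
    selection = list(termination = 5, cv_folds = 5, seed = 1, screen_top = 24),
    nodes = list(phi1 = "tree", phi2 = "lda"),
    therapy = list(profile = 2))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg$hash <- string_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  class(cfg) <- "run_config"
  cfg
}

config_to_spec <- function(cfg) {
  bhc_spec(phi1 = cfg$nodes$phi1, phi2 = cfg$nodes$phi2,
           screen_top = cfg$selection$screen_top,
           termination = cfg$selection$termination,
           cv_folds = cfg$selection$cv_folds,
           seed = cfg$selection$seed)
}
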