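#' @title The 379-region parcellation atlas and its network affiliations
#' @description
#' All downstream results in this package are expressed in the coordinate
#' system of a 379-region whole-brain parcellation (the HCP-MMP1 scheme:
#' 180 cortical parcels per hemisphere, 9 subcortical structures per
#' hemisphere, and the brainstem as a single midline parcel). Each region
#' carries exactly one large-scale network affiliation, used as the
#' aggregation ontology for feature importance and anomaly counts.
#' @name atlas
NULL

# Glasser short codes for the 180 cortical parcels (one hemisphere).
.glasser_codes <- c(
  "V1", "MST", "V6", "V2", "V3", "V4", "V8", "4", "3b", "FEF",
  "PEF", "55b", "V3A", "RSC", "POS2", "V7", "IPS1", "FFC", "V3B", "LO1",
  "LO2", "PIT", "MT", "A1", "PSL", "SFL", "PCV", "STV", "7Pm", "7m",
  "POS1", "23d", "v23ab", "d23ab", "31pv", "5m", "5mv", "23c", "5L", "24dd",
  "24dv", "7AL", "SCEF", "6ma", "7Am", "7PL", "7PC", "LIPv", "VIP", "MIP",
  "1", "2", "3a", "6d", "6mp", "6v", "p24pr", "33pr", "a24pr", "p32pr",
  "a24", "d32", "8BM", "p32", "10r", "47m", "8Av", "8Ad", "9m", "8BL",
  "9p", "10d", "8C", "44", "45", "47l", "a47r", "6r", "IFJa", "IFJp",
  "IFSp", "IFSa", "p9-46v", "46", "a9-46v", "9-46d", "9a", "10v", "a10p", "10pp",
  "11l", "13l", "OFC", "47s", "LIPd", "6a", "i6-8", "s6-8", "43", "OP4",
  "OP1", "OP2-3", "52", "RI", "PFcm", "PoI2", "TA2", "FOP4", "MI", "Pir",
  "AVI", "AAIC", "FOP1", "FOP3", "FOP2", "PFt", "AIP", "EC", "PreS", "H",
  "ProS", "PeEc", "STGa", "PBelt", "A5", "PHA1", "PHA3", "STSda", "STSdp", "STSvp",
  "TGd", "TE1a", "TE1p", "TE2a", "TF", "TE2p", "PHT", "PH", "TPOJ1", "TPOJ2",
  "TPOJ3", "DVT", "PGp", "IP2", "IP1", "IP0", "PFop", "PF", "PFm", "PGi",
  "PGs", "V6A", "VMV1", "VMV3", "PHA2", "V4t", "FST", "V3CD", "LO3", "VMV2",
  "31pd", "31a", "VVC", "25", "s32", "pOFC", "PoI1", "Ig", "FOP5", "p10p",
  "p47r", "TGv", "MBelt", "LBelt", "A4", "STSva", "TE1m", "PI", "a32pr", "p24"
)

.subcortical_codes <- c(
  "Accumbens", "Amygdala", "Caudate", "Cerebellum", "Diencephalon",
  "Hippocampus", "Pallidum", "Putamen", "Thalamus"
)

#' Valid large-scale network labels
#'
#' @return Character vector of the permitted network labels, including
#'   `"Unassigned"` for regions without a confident affiliation.
#' @export
network_labels <- function() {
  c("CEN", "DMN", "DAN", "Limbic", "Salience", "Sensorimotor", "Visual",
    "Language", "AccessoryLanguage", "Auditory", "MultipleDemand", "VAN",
    "MedialTemporal", "Unassigned")
}

# Default bilateral network map: parcel short code -> network label.
# Left-hemisphere overrides below implement the left-lateralized language
# and accessory language systems.
.base_network_map <- function() {
  grp <- list(
    Visual = c("V1", "MST", "V6", "V2", "V3", "V4", "V8", "V3A", "V7",
               "FFC", "V3B", "LO1", "LO2", "PIT", "MT", "V6A", "VMV1",
               "VMV2", "VMV3", "V4t", "FST", "V3CD", "LO3", "VVC", "DVT",
               "ProS", "PH"),
    Sensorimotor = c("4", "3a", "3b", "1", "2", "5m", "5mv", "5L", "24dd",
                     "24dv", "6d", "6mp", "6v", "6ma", "OP1", "OP2-3",
                     "OP4", "43", "FOP1", "PFt"),
    Auditory = c("A1", "MBelt", "LBelt", "PBelt", "A4", "A5", "RI", "TA2",
                 "52"),
    DAN = c("FEF", "PEF", "LIPv", "VIP", "MIP", "7AL", "7Am", "7PL", "7PC",
            "AIP", "6a", "IPS1", "IP0", "PGp"),
    Salience = c("23c", "a24pr", "p24pr", "p32pr", "a32pr", "AVI", "MI",
                 "FOP2", "FOP3", "FOP4", "FOP5", "PoI1", "PoI2", "Ig",
                 "PI", "SCEF"),
    CEN = c("46", "9-46d", "a9-46v", "p9-46v", "IFSp", "IFSa", "IFJp",
            "IFJa", "i6-8", "s6-8", "8C", "p47r", "a47r", "47l", "LIPd",
            "IP1", "IP2", "POS2", "AAIC", "33pr", "p24", "31a", "PFm",
            "44", "45"),
    DMN = c("RSC", "POS1", "23d", "v23ab", "d23ab", "31pv", "31pd", "7m",
            "7Pm", "10d", "10r", "10v", "9m", "9a", "9p", "8Ad", "8Av",
            "8BL", "PGi", "PGs", "PCV", "STGa", "TGd", "TE1m", "TE2a",
            "TE2p", "PHA2", "SFL", "STSda", "STSdp", "STSva", "STSvp",
            "TE1a", "TE1p", "PHT", "TGv"),
    Limbic = c("OFC", "pOFC", "47m", "47s", "11l", "13l", "25", "s32",
               "p32", "a24", "d32", "10pp", "a10p", "p10p", "Pir"),
    MedialTemporal = c("H", "PreS", "EC", "PeEc", "PHA1", "PHA3", "TF"),
    VAN = c("TPOJ1", "TPOJ2", "TPOJ3", "STV", "PSL", "PF", "PFop", "PFcm",
            "6r"),
    MultipleDemand = c("55b", "8BM")
  )
  map <- stats::setNames(rep("Unassigned", length(.glasser_codes)),
                         .glasser_codes)
  for (net in names(grp)) map[grp[[net]]] <- net
  map
}

# Left-hemisphere language system per the scheme used throughout:
# 15 language parcels and 4 accessory-language parcels.
.language_left <- c("55b", "8C", "44", "45", "8BM", "IFJa", "AIP", "PFm",
                    "SFL", "SCEF", "PBelt", "STSdp", "STSvp", "TE1p", "PHT")
.accessory_language_left <- c("STSda", "TE1a", "TGv", "STSva")

#' Build the default 379-region atlas registry
#'
#' Constructs the packaged default parcellation: 180 cortical parcels per
#' hemisphere (Glasser short codes, named `L_<code>` / `R_<code>`),
#' 9 subcortical structures per hemisphere, and the midline brainstem.
#' Network affiliations follow a Yeo-style scheme extended with the
#' left-lateralized Language and AccessoryLanguage systems, the Auditory
#' system, the MultipleDemand network, the VAN and a MedialTemporal
#' system; regions without a confident affiliation are `"Unassigned"`.
#'
#' @return An `atlas_registry`: a data.frame with columns `region_id`,
#'   `name`, `hemisphere`, `kind`, `network`, one row per region,
#'   `region_id` ascending 1..379.
#' @examples
#' atlas <- build_default_atlas()
#' nrow(atlas)                 # 379
#' network_of(atlas, "L_45")   # "Language"
#' @export
build_default_atlas <- function() {
  base <- .base_network_map()
  left <- base
  left[.language_left] <- "Language"
  left[.accessory_language_left] <- "AccessoryLanguage"

  sub_net <- stats::setNames(rep("Unassigned", length(.subcortical_codes)),
                             .subcortical_codes)
  sub_net[c("Hippocampus", "Amygdala")] <- "MedialTemporal"

  df <- rbind(
    data.frame(name = paste0("L_", .glasser_codes), hemisphere = "left",
               kind = "cortical", network = unname(left),
               stringsAsFactors = FALSE),
    data.frame(name = paste0("R_", .glasser_codes), hemisphere = "right",
               kind = "cortical", network = unname(base),
               stringsAsFactors = FALSE),
    data.frame(name = paste0("L_", .subcortical_codes), hemisphere = "left",
               kind = "subcortical", network = unname(sub_net),
               stringsAsFactors = FALSE),
    data.frame(name = paste0("R_", .subcortical_codes), hemisphere = "right",
               kind = "subcortical", network = unname(sub_net),
               stringsAsFactors = FALSE),
    data.frame(name = "M_Brainstem", hemisphere = "midline",
               kind = "brainstem", network = "Unassigned",
               stringsAsFactors = FALSE)
  )
  df <- cbind(region_id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  validate_atlas(df)
}

#' Validate and classify an atlas registry
#'
#' Checks the structural invariants of a region table: exactly 379 rows,
#' contiguous unique ids 1..379, unique names, 180 cortical parcels per
#' hemisphere, 9 subcortical per hemisphere, one midline brainstem region,
#' and known network labels.
#'
#' @param df data.frame with columns `region_id`, `name`, `hemisphere`,
#'   `kind`, `network`.
#' @return The input, ordered by `region_id`, with class `atlas_registry`.
#' @export
validate_atlas <- function(df) {
  required <- c("region_id", "name", "hemisphere", "kind", "network")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("atlas table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) != 379L)
    stop("atlas must contain exactly 379 regions, got ", nrow(df))
  if (anyDuplicated(df$region_id))
    stop("duplicate region_id in atlas table")
  if (!identical(sort(as.integer(df$region_id)), 1:379))
    stop("region_id must be the contiguous set 1..379")
  if (anyDuplicated(df$name))
    stop("duplicate region name in atlas table")
  bad <- setdiff(unique(df$network), network_labels())
  if (length(bad) > 0)
    stop("unknown network label(s): ", paste(bad, collapse = ", "))
  counts <- table(df$kind, df$hemisphere)
  ok <- function(kind, hemi, n) {
    kind %in% rownames(counts) && hemi %in% colnames(counts) &&
      counts[kind, hemi] == n
  }
  if (!ok("cortical", "left", 180L) || !ok("cortical", "right", 180L))
    stop("atlas must contain exactly 180 cortical regions per hemisphere")
  if (!ok("subcortical", "left", 9L) || !ok("subcortical", "right", 9L))
    stop("atlas must contain exactly 9 subcortical regions per hemisphere")
  if (sum(df$kind == "brainstem") != 1L ||
      df$hemisphere[df$kind == "brainstem"] != "midline")
    stop("atlas must contain exactly 1 midline brainstem region")
  df <- df[order(df$region_id), required]
  df$region_id <- as.integer(df$region_id)
  rownames(df) <- NULL
  class(df) <- c("atlas_registry", "data.frame")
  df
}

#' Read a region/network affiliation table
#'
#' Reads a CSV with header `region_id,name,hemisphere,kind,network` and
#' validates it as a 379-region registry. Round-trips with
#' [write_affiliation_table()].
#'
#' @param path Path to the CSV file.
#' @return An `atlas_registry`.
#' @export
load_affiliation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_id = "integer"))
  validate_atlas(df)
}

#' Write a region/network affiliation table
#'
#' @param atlas An `atlas_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_affiliation_table <- function(atlas, path) {
  stopifnot(inherits(atlas, "atlas_registry"))
  utils::write.csv(as.data.frame(atlas), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Resolve a region given by name or id to its row index; errors if unknown.
resolve_region <- function(atlas, region) {
  if (is.numeric(region)) {
    idx <- match(as.integer(region), atlas$region_id)
  } else {
    idx <- match(as.character(region), atlas$name)
  }
  if (anyNA(idx))
    stop("unknown region(s): ",
         paste(region[is.na(idx)], collapse = ", "))
  idx
}

#' Network affiliation of a region
#'
#' @param atlas An `atlas_registry`.
#' @param region Region name (e.g. `"L_45"`) or integer id; vectorized.
#' @return Character vector of network labels.
#' @examples
#' network_of(build_default_atlas(), c("L_45", "L_23c"))
#' @export
network_of <- function(atlas, region) {
  atlas$network[resolve_region(atlas, region)]
}

#' @export
print.atlas_registry <- function(x, ...) {
  cat("<atlas_registry> 379 regions,",
      length(setdiff(unique(x$network), "Unassigned")), "networks\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
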