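#' Synthetic CAZy family/EC to substrate map
#'
#' A SYNTHETIC substrate map for simulation and testing: plausible
#' (CAZy family, EC number) pairs mapped to glycan substrate groups and their
#' three source categories — Plant-glycans (plant and algae polysaccharides),
#' Host-glycans (animal glycoproteins, proteoglycans, cerebrosides, lactose,
#' milk oligosaccharides, ...) and Microbial-glycans (bacterial and fungal
#' cell-wall polymers). It is NOT a curated annotation resource: family/EC
#' assignments are illustrative stand-ins for a real BRENDA/CAZy-derived
#' table, which users supply for real analyses. Rows with a blank EC act as
#' family-level fallbacks in [assign_substrates()].
#'
#' The default map covers 50 substrate groups, enough to exercise the
#' bootstrap machinery at a realistic breadth.
#'
#' @return data.frame with columns `family`, `ec`, `substrate`, `source`.
#' @export
default_substrate_map <- function() {
  rec <- function(family, ec, substrate, source)
    data.frame(family = family, ec = ec, substrate = substrate,
               source = source, stringsAsFactors = FALSE)
  plant <- rbind(
    rec("GH13", "3.2.1.1",   "starch",                "Plant-glycans"),
    rec("GH13", "",          "starch",                "Plant-glycans"),
    rec("GH97", "3.2.1.20",  "starch",                "Plant-glycans"),
    rec("GH5",  "3.2.1.4",   "cellulose",             "Plant-glycans"),
    rec("GH9",  "3.2.1.4",   "cellulose",             "Plant-glycans"),
    rec("GH10", "3.2.1.8",   "xylan",                 "Plant-glycans"),
    rec("GH43", "3.2.1.37",  "xylan",                 "Plant-glycans"),
    rec("GH74", "3.2.1.151", "xyloglucan",            "Plant-glycans"),
    rec("GH43", "3.2.1.55",  "arabinan",              "Plant-glycans"),
    rec("GH51", "3.2.1.55",  "arabinan",              "Plant-glycans"),
    rec("GH53", "3.2.1.89",  "arabinogalactan",       "Plant-glycans"),
    rec("GH26", "3.2.1.78",  "galactomannan",         "Plant-glycans"),
    rec("GH5",  "3.2.1.25",  "glucomannan",           "Plant-glycans"),
    rec("GH28", "3.2.1.15",  "pectin",                "Plant-glycans"),
    rec("PL1",  "4.2.2.2",   "pectin",                "Plant-glycans"),
    rec("GH105","3.2.1.172", "rhamnogalacturonan",    "Plant-glycans"),
    rec("PL11", "4.2.2.23",  "rhamnogalacturonan",    "Plant-glycans"),
    rec("CE8",  "3.1.1.11",  "polygalacturonan",      "Plant-glycans"),
    rec("GH146","3.2.1.185", "beta-1,2-arabinan",     "Plant-glycans"),
    rec("GH17", "3.2.1.39",  "beta-1,3-glucan",       "Plant-glycans"),
    rec("GH16", "3.2.1.73",  "mixed-linkage glucan",  "Plant-glycans"),
    rec("GH32", "3.2.1.7",   "inulin",                "Plant-glycans"),
    rec("GH32", "3.2.1.26",  "sucrose",               "Plant-glycans"),
    rec("GH36", "3.2.1.22",  "raffinose",             "Plant-glycans"),
    rec("GH2",  "3.2.1.23",  "galactan",              "Plant-glycans"),
    rec("GH35", "3.2.1.23",  "plant mannan",          "Plant-glycans"),
    rec("GH38", "3.2.1.24",  "plant mannan",          "Plant-glycans"),
    rec("GH16", "3.2.1.81",  "agarose",               "Plant-glycans"),
    rec("PL7",  "4.2.2.3",   "alginate",              "Plant-glycans"),
    rec("AA10", "",          "crystalline cellulose", "Plant-glycans"))
  host <- rbind(
    rec("GH33", "3.2.1.18",  "sialylated glycans",    "Host-glycans"),
    rec("GH20", "3.2.1.52",  "glycoprotein",          "Host-glycans"),
    rec("GH84", "3.2.1.169", "glycoprotein",          "Host-glycans"),
    rec("GH18", "3.2.1.96",  "N-glycans",             "Host-glycans"),
    rec("GH101","3.2.1.97",  "mucin O-glycans",       "Host-glycans"),
    rec("GH129","",          "mucin O-glycans",       "Host-glycans"),
    rec("GH79", "3.2.1.31",  "glucuronides",          "Host-glycans"),
    rec("GH2",  "3.2.1.31",  "glucuronides",          "Host-glycans"),
    rec("GH88", "3.2.1.-",   "proteoglycan",          "Host-glycans"),
    rec("PL8",  "4.2.2.1",   "hyaluronan",            "Host-glycans"),
    rec("PL8",  "4.2.2.5",   "chondroitin sulfate",   "Host-glycans"),
    rec("PL12", "4.2.2.8",   "heparan sulfate",       "Host-glycans"),
    rec("GH2",  "3.2.1.108", "lactose",               "Host-glycans"),
    rec("GH42", "3.2.1.108", "lactose",               "Host-glycans"),
    rec("GH112","2.4.1.211", "milk oligosaccharides", "Host-glycans"),
    rec("GH95", "3.2.1.51",  "fucosylated glycans",   "Host-glycans"),
    rec("GH30", "3.2.1.45",  "cerebrosides",          "Host-glycans"),
    rec("GH123","3.2.1.53",  "galactosamine glycans", "Host-glycans"))
  microbial <- rbind(
    rec("GH23", "4.2.2.n1",  "peptidoglycan",         "Microbial-glycans"),
    rec("GH25", "3.2.1.17",  "peptidoglycan",         "Microbial-glycans"),
    rec("GH18", "3.2.1.14",  "chitin",                "Microbial-glycans"),
    rec("GH19", "3.2.1.14",  "chitin",                "Microbial-glycans"),
    rec("GH46", "3.2.1.132", "chitosan",              "Microbial-glycans"),
    rec("GH76", "3.2.1.101", "yeast alpha-mannan",    "Microbial-glycans"),
    rec("GH30", "3.2.1.75",  "beta-1,6-glucan",       "Microbial-glycans"),
    rec("GH66", "3.2.1.11",  "dextran",               "Microbial-glycans"),
    rec("GH32", "3.2.1.65",  "levan",                 "Microbial-glycans"),
    rec("GH13", "3.2.1.41",  "pullulan",              "Microbial-glycans"),
    rec("GH13", "3.2.1.68",  "glycogen",              "Microbial-glycans"),
    rec("GH64", "3.2.1.58",  "curdlan",               "Microbial-glycans"),
    rec("GH55", "3.2.1.59",  "fungal beta-glucan",    "Microbial-glycans"),
    rec("CE4",  "3.5.1.41",  "bacterial EPS",         "Microbial-glycans"),
    rec("CE9",  "3.5.99.6",  "amino sugars",          "Microbial-glycans"),
    rec("GH103","4.2.2.n2",  "murein glycan strands", "Microbial-glycans"))
  map <- rbind(plant, host, microbial)
  validate_substrate_map(map)
  map
}

validate_substrate_map <- function(map) {
  need <- c("family", "ec", "substrate", "source")
  if (!all(need %in% names(map)))
    stop("substrate map needs columns: ", paste(need, collapse = ", "))
  if (nrow(map) == 0) stop("substrate map is empty")
  key <- paste(map$family, map$ec)
  if (anyDuplicated(key))
    stop("duplicate (family, EC) keys in substrate map: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ok <- c("Plant-glycans", "Host-glycans", "Microbial-glycans")
  if (!all(map$source %in% ok))
    stop("source category must be one of: ", paste(ok, collapse = ", "))
  invisible(map)
}
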