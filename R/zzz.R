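.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".N", "A_ij", "Fw", "P_ij", "area", "carea", "cell", "cell_id",
  "class", "cpop", "den", "dens", "f", "fine_id", "i.n", "i.uarea", "n",
  "num", "parcel", "parent_id", "pop", "stratum", "t", "uarea", "w2", "wa",
  "warea", "weight"
))
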