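{
  "TNK": {
    "positive": ["CD3D", "CD3E", "CD2", "IL7R", "NKG7", "GNLY", "KLRD1"]
  },
  "MPh": {
    "positive": ["CD14", "LYZ", "FCGR3A", "CD68", "ITGAM", "CSF1R"]
  },
  "BPC": {
    "positive": ["CD79A", "CD79B", "MS4A1", "IGHM", "JCHAIN"]
  },
  "CD4T": {
    "positive": ["CD3D", "CD3E", "CD4", "IL7R"],
    "negative": ["CD8A", "CD8B"]
  },
  "CD8T": {
    "positive": ["CD3D", "CD3E", "CD8A", "CD8B"],
    "negative": ["CD4"]
  }
}
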