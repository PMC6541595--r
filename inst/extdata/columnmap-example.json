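{
  "cell_id": "Cell ID",
  "colony_id": "Colony",
  "condition": "Medium",
  "frame": "Frame",
  "time_h": "Time (h)",
  "x": "Centroid X",
  "y": "Centroid Y",
  "nuclear_area": "Nucleus Area",
  "cherry": "Ch2 Mean",
  "venus": "Ch3 Mean",
  "parent_id": "Parent ID"
}
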