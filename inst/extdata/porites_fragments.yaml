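# Metadata for the twelve Porites skeletal fragments selected for
# intra-colonial profile analysis. green_band_mm is the stereoscope-measured
# green-band interval on the vertical profile (mm, apical end = 0);
# z_length_mm is the vertical length recorded by the porosity map.
fragments:
  - id: 15G
    species: P. panamensis
    location: Pacific
    depth_m: 12
    green_band_mm: [1.1, 2.2]
    z_length_mm: 7
    selected: true
  - id: 28G
    species: P. panamensis
    location: Pacific
    depth_m: 12
    green_band_mm: [1.7, 2.9]
    z_length_mm: 9
    selected: true
  - id: 36G
    species: P. panamensis
    location: Pacific
    depth_m: 12
    green_band_mm: [1.6, 2.3]
    z_length_mm: 7
    selected: true
  - id: 47G
    species: P. panamensis
    location: Pacific
    depth_m: 12
    green_band_mm: [1.4, 2.6]
    z_length_mm: 7
    selected: true
  - id: 10G
    species: P. lobata
    location: Pacific
    depth_m: 12
    green_band_mm: [2.3, 3.2]
    z_length_mm: 7
    selected: true
  - id: 19G
    species: P. lobata
    location: Pacific
    depth_m: 12
    green_band_mm: [1.5, 3.6]
    z_length_mm: 8
    selected: true
  - id: 26G
    species: P. lobata
    location: Pacific
    depth_m: 12
    green_band_mm: [1.9, 3.9]
    z_length_mm: 8
    selected: true
  - id: 39G
    species: P. lobata
    location: Pacific
    depth_m: 12
    green_band_mm: [1.7, 3.4]
    z_length_mm: 7
    selected: true
  - id: A10
    species: P. astreoides
    location: Caribbean
    depth_m: 35
    green_band_mm: [1.8, 2.8]
    z_length_mm: 5
    selected: true
  - id: A11
    species: P. astreoides
    location: Caribbean
    depth_m: 35
    green_band_mm: [1.5, 1.9]
    z_length_mm: 7
    selected: true
  - id: A3
    species: P. astreoides
    location: Caribbean
    depth_m: 9
    green_band_mm: [2.3, 3.8]
    z_length_mm: 7
    selected: true
  - id: A5
    species: P. astreoides
    location: Caribbean
    depth_m: 10
    green_band_mm: [2.2, 3.2]
    z_length_mm: 6
    selected: true
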