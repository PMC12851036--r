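{
  "format": "gazeStrain-hess-1",
  "eye": "left",
  "fixating_eye": "right",
  "geometry": {
    "viewing_distance": 0.5,
    "grid_step": 5,
    "inner_field_half_width": 15
  },
  "points": [
    {
      "position_id": 1,
      "position": "center",
      "target_deg": [0, 0],
      "measured_deg": [0, 0],
      "n": 1
    },
    {
      "position_id": 2,
      "position": "up",
      "target_deg": [0, 15],
      "measured_deg": [0, 15],
      "n": 1
    },
    {
      "position_id": 3,
      "position": "up_right",
      "target_deg": [15, 15],
      "measured_deg": [15, 15],
      "n": 1
    },
    {
      "position_id": 4,
      "position": "right",
      "target_deg": [15, 0],
      "measured_deg": [15, 0],
      "n": 1
    },
    {
      "position_id": 5,
      "position": "down_right",
      "target_deg": [15, -15],
      "measured_deg": [15, -15],
      "n": 1
    },
    {
      "position_id": 6,
      "position": "down",
      "target_deg": [0, -15],
      "measured_deg": [0, -15],
      "n": 1
    },
    {
      "position_id": 7,
      "position": "down_left",
      "target_deg": [-15, -15],
      "measured_deg": [-15, -15],
      "n": 1
    },
    {
      "position_id": 8,
      "position": "left",
      "target_deg": [-15, 0],
      "measured_deg": [-15, 0],
      "n": 1
    },
    {
      "position_id": 9,
      "position": "up_left",
      "target_deg": [-15, 15],
      "measured_deg": [-15, 15],
      "n": 1
    }
  ]
}
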