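# Default synthetic insole sensor layout (stand-in coordinates).
#
# 16 force-sensitive resistors on a right-foot insole: sensors 1-12 under the
# forefoot (three rows of four across the toes and metatarsal heads), sensors
# 13-16 under the heel. Coordinates are millimetres, origin at the
# posterior-lateral heel corner, x increasing medially (medio-lateral),
# y increasing anteriorly (anterior-posterior). These coordinates are a
# plausible stand-in for an unpublished commercial layout; substitute a
# measured layout file for real hardware.
sensors:
  - {sensor_id: 1,  "x": 18, "y": 228, region: forefoot}
  - {sensor_id: 2,  "x": 40, "y": 234, region: forefoot}
  - {sensor_id: 3,  "x": 62, "y": 230, region: forefoot}
  - {sensor_id: 4,  "x": 82, "y": 218, region: forefoot}
  - {sensor_id: 5,  "x": 16, "y": 196, region: forefoot}
  - {sensor_id: 6,  "x": 38, "y": 200, region: forefoot}
  - {sensor_id: 7,  "x": 62, "y": 198, region: forefoot}
  - {sensor_id: 8,  "x": 84, "y": 188, region: forefoot}
  - {sensor_id: 9,  "x": 18, "y": 164, region: forefoot}
  - {sensor_id: 10, "x": 40, "y": 168, region: forefoot}
  - {sensor_id: 11, "x": 62, "y": 166, region: forefoot}
  - {sensor_id: 12, "x": 82, "y": 158, region: forefoot}
  - {sensor_id: 13, "x": 30, "y": 58,  region: rearfoot}
  - {sensor_id: 14, "x": 58, "y": 58,  region: rearfoot}
  - {sensor_id: 15, "x": 32, "y": 28,  region: rearfoot}
  - {sensor_id: 16, "x": 58, "y": 28,  region: rearfoot}
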