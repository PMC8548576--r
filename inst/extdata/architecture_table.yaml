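# Machine-readable internal architecture table of the default backbone at
# its reference input (416 x 416 x 3). Shapes are [height, width, channels].
# The contract-test suite walks these rows against profile_model().
# The final entry (head_row) is the single-class detection head formula
# applied at the deepest scale -- it is not a backbone tap and is excluded
# from the row-by-row shape walk.
reference_input: 416
rows:
  - block: "Down-sampling method based on cross-scale fusion"
    filters: "1x1x32 3x3x32 (Stride = 2) 1x1x32"
    in: [416, 416, 3]
    out: [208, 208, 32]
  - block: "Down-sampling method based on cross-scale fusion"
    filters: "1x1x64 3x3x64 (Stride = 2) 1x1x64"
    in: [208, 208, 32]
    out: [104, 104, 64]
  - block: "Light-CSP block"
    filters: "3x3x64 3x3x32 3x3x32"
    in: [104, 104, 64]
    out: [104, 104, 64]
  - block: "(Transition filter)"
    filters: "1x1x64"
    in: [104, 104, 64]
    out: [104, 104, 128]
  - block: "Maxpool"
    filters: "Stride = 2"
    in: [104, 104, 128]
    out: [52, 52, 128]
  - block: "Light-CSP block"
    filters: "3x3x128 3x3x64 3x3x64"
    in: [52, 52, 128]
    out: [52, 52, 128]
  - block: "(Transition filter)"
    filters: "1x1x128"
    in: [52, 52, 128]
    out: [52, 52, 256]
  - block: "Maxpool"
    filters: "Stride = 2"
    in: [52, 52, 256]
    out: [26, 26, 256]
  - block: "Light-CSP block"
    filters: "3x3x256 3x3x128 3x3x128"
    in: [26, 26, 256]
    out: [26, 26, 256]
  - block: "(Transition filter)"
    filters: "1x1x256"
    in: [26, 26, 256]
    out: [26, 26, 512]
  - block: "Maxpool"
    filters: "Stride = 2"
    in: [26, 26, 512]
    out: [13, 13, 512]
  - block: "Light-CSP block"
    filters: "3x3x512 3x3x256 3x3x256"
    in: [13, 13, 512]
    out: [13, 13, 512]
head_row:
  block: "(Transition filter)"
  filters: "1x1x512"
  in: [13, 13, 512]
  out: [13, 13, 18]
  role: detection_head
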