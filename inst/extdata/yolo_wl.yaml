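# YOLO-WL layer manifest. One row per layer: `from` lists source row indices
# (-1 = previous row); `params` is the published expected parameter count.
# Row 5 additionally carries `corrected_params`: the printed per-row sum
# differs from the printed total by exactly 360 = 1408 - 1048, identifying
# the printed 1048 as a transposition of the constructed 1408.
name: yolo-wl
nc: 6
reference_input: 640
summary:
  total_params: 1394688
  trainable_params: 1394672
  gflops: 9.9
layers:
- {index: 0, from: [-1], repeats: 1, module: GCBS, args: [3, 16, 3, 2], params: 464}
- {index: 1, from: [-1], repeats: 1, module: GCBS, args: [16, 32, 3, 2], params: 352}
- {index: 2, from: [-1], repeats: 1, module: C2f-MSDDSC, args: [32, 32, 1], params: 11882}
- {index: 3, from: [-1], repeats: 1, module: GCBS, args: [32, 64, 3, 2], params: 704}
- {index: 4, from: [-1], repeats: 2, module: C2f-MSDDSC, args: [64, 64, 2], params: 82916}
- {index: 5, from: [-1], repeats: 1, module: GCBS, args: [64, 128, 3, 2], params: 1048,
   corrected_params: 1408,
   note: "printed 1048 is a transposition of 1408; per-row sum vs printed total differs by exactly 360"}
- {index: 6, from: [-1], repeats: 2, module: C2f-MSDDSC, args: [128, 128, 2], params: 325380}
- {index: 7, from: [-1], repeats: 1, module: GCBS, args: [128, 128, 3, 2], params: 1408}
- {index: 8, from: [-1], repeats: 1, module: C2f-MSDDSC, args: [128, 128, 1], params: 179330}
- {index: 9, from: [-1], repeats: 1, module: SPPF, args: [128, 128, 5], params: 41344}
- {index: 10, from: [-1], repeats: 1, module: Upsample, args: [~, 2, nearest], params: 0}
- {index: 11, from: [-1, 6], repeats: 1, module: SGF-2, args: [1], params: 102}
- {index: 12, from: [-1], repeats: 1, module: C2f, args: [256, 128, 1], params: 131840}
- {index: 13, from: [-1], repeats: 1, module: Upsample, args: [~, 2, nearest], params: 0}
- {index: 14, from: [-1, 4], repeats: 1, module: SGF-2, args: [1], params: 102}
- {index: 15, from: [-1], repeats: 1, module: C2f, args: [192, 64, 1], params: 37248}
- {index: 16, from: [-1], repeats: 1, module: Upsample, args: [~, 2, nearest], params: 0}
- {index: 17, from: [-1, 2], repeats: 1, module: SGF-2, args: [1], params: 102}
- {index: 18, from: [-1], repeats: 1, module: C2f, args: [96, 32, 1], params: 9408}
- {index: 19, from: [-1], repeats: 1, module: MLKSA, args: [32], params: 990}
- {index: 20, from: [-1], repeats: 1, module: Conv, args: [32, 32, 3, 2], params: 9280}
- {index: 21, from: [-1, 4, 15], repeats: 1, module: SGF-3, args: [1], params: 103}
- {index: 22, from: [-1], repeats: 1, module: C2f, args: [160, 64, 1], params: 35200}
- {index: 23, from: [-1], repeats: 1, module: MLKSA, args: [64], params: 990}
- {index: 24, from: [-1], repeats: 1, module: Conv, args: [64, 64, 3, 2], params: 36992}
- {index: 25, from: [-1, 6, 12], repeats: 1, module: SGF-3, args: [1], params: 103}
- {index: 26, from: [-1], repeats: 1, module: C2f, args: [320, 128, 1], params: 140032}
- {index: 27, from: [-1], repeats: 1, module: MLKSA, args: [128], params: 990}
- {index: 28, from: [19, 23, 27], repeats: 1, module: Detect, args: [6, [32, 64, 128]], params: 346018}
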