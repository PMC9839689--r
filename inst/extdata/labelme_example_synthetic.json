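{
  "version": "5.0.1",
  "shapes": [
    {
      "label": "wound",
      "points": [
        [
          96,
          120
        ],
        [
          380,
          88
        ],
        [
          420,
          360
        ],
        [
          180,
          430
        ]
      ],
      "shape_type": "polygon"
    }
  ],
  "imageWidth": 512,
  "imageHeight": 512
}
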