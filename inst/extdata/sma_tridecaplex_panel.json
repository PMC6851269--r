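{
  "chrom": "chr5",
  "duplicon": {
    "start": 69000000,
    "end": 70700000
  },
  "gene_position_bp": 70220000,
  "markers": [
    {
      "name": "D5S1417",
      "chrom": "chr5",
      "position_bp": 68520000,
      "side": "upstream",
      "motif": "TG",
      "size_min": 206,
      "size_max": 228,
      "he_chinese": 0.69,
      "he_caucasian": 0.75,
      "ho_chinese": 0.63,
      "ho_caucasian": 0.7
    },
    {
      "name": "D5S1413",
      "chrom": "chr5",
      "position_bp": 68600000,
      "side": "upstream",
      "motif": "GT",
      "size_min": 143,
      "size_max": 167,
      "he_chinese": 0.62,
      "he_caucasian": 0.56,
      "ho_chinese": 0.63,
      "ho_caucasian": 0.59
    },
    {
      "name": "SMA6863",
      "chrom": "chr5",
      "position_bp": 68700000,
      "side": "upstream",
      "motif": "GA",
      "size_min": 348,
      "size_max": 384,
      "he_chinese": 0.81,
      "he_caucasian": 0.71,
      "ho_chinese": 0.84,
      "ho_caucasian": 0.69
    },
    {
      "name": "SMA6873",
      "chrom": "chr5",
      "position_bp": 68790000,
      "side": "upstream",
      "motif": "AC",
      "size_min": 295,
      "size_max": 327,
      "he_chinese": 0.82,
      "he_caucasian": 0.76,
      "ho_chinese": 0.77,
      "ho_caucasian": 0.78
    },
    {
      "name": "D5S1370",
      "chrom": "chr5",
      "position_bp": 68870000,
      "side": "upstream",
      "motif": "TG",
      "size_min": 177,
      "size_max": 193,
      "he_chinese": 0.68,
      "he_caucasian": 0.52,
      "ho_chinese": 0.68,
      "ho_caucasian": 0.57
    },
    {
      "name": "SMA6877",
      "chrom": "chr5",
      "position_bp": 68960000,
      "side": "upstream",
      "motif": "TG",
      "size_min": 271,
      "size_max": 293,
      "he_chinese": 0.81,
      "he_caucasian": 0.79,
      "ho_chinese": 0.83,
      "ho_caucasian": 0.8
    },
    {
      "name": "D5S1408",
      "chrom": "chr5",
      "position_bp": 70730000,
      "side": "downstream",
      "motif": "AC",
      "size_min": 246,
      "size_max": 274,
      "he_chinese": 0.76,
      "he_caucasian": 0.72,
      "ho_chinese": 0.79,
      "ho_caucasian": 0.7
    },
    {
      "name": "SMA7093",
      "chrom": "chr5",
      "position_bp": 70800000,
      "side": "downstream",
      "motif": "TG",
      "size_min": 178,
      "size_max": 206,
      "he_chinese": 0.57,
      "he_caucasian": 0.61,
      "ho_chinese": 0.57,
      "ho_caucasian": 0.56
    },
    {
      "name": "D5S610",
      "chrom": "chr5",
      "position_bp": 70880000,
      "side": "downstream",
      "motif": "TG",
      "size_min": 143,
      "size_max": 175,
      "he_chinese": 0.84,
      "he_caucasian": 0.8,
      "ho_chinese": 0.8,
      "ho_caucasian": 0.8
    },
    {
      "name": "SMA7115",
      "chrom": "chr5",
      "position_bp": 70960000,
      "side": "downstream",
      "motif": "AG",
      "size_min": 281,
      "size_max": 311,
      "he_chinese": 0.81,
      "he_caucasian": 0.84,
      "ho_chinese": 0.85,
      "ho_caucasian": 0.81
    },
    {
      "name": "SMA7120",
      "chrom": "chr5",
      "position_bp": 71050000,
      "side": "downstream",
      "motif": "AC",
      "size_min": 307,
      "size_max": 325,
      "he_chinese": 0.75,
      "he_caucasian": 0.79,
      "ho_chinese": 0.75,
      "ho_caucasian": 0.75
    },
    {
      "name": "D5S1999",
      "chrom": "chr5",
      "position_bp": 71130000,
      "side": "downstream",
      "motif": "GA",
      "size_min": 319,
      "size_max": 327,
      "he_chinese": 0.62,
      "he_caucasian": 0.52,
      "ho_chinese": 0.62,
      "ho_caucasian": 0.6
    },
    {
      "name": "D5S637",
      "chrom": "chr5",
      "position_bp": 71210000,
      "side": "downstream",
      "motif": "CA",
      "size_min": 235,
      "size_max": 243,
      "he_chinese": 0.52,
      "he_caucasian": 0.74,
      "ho_chinese": 0.54,
      "ho_caucasian": 0.86
    }
  ]
}
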