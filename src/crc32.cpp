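#include <Rcpp.h>

// CRC-32 (IEEE 802.3 polynomial), used by the minimal xlsx zip writer.

// [[Rcpp::export]]
double crc32_cpp(Rcpp::RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = (crc >> 8) ^ table[(crc ^ data[i]) & 0xFFu];
  crc ^= 0xFFFFFFFFu;
  return (double)crc;
}
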