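#include <Rcpp.h>
#include <zlib.h>

using namespace Rcpp;

// Raw-deflate (no zlib/gzip wrapper) a payload at the given compression level.
// BGZF blocks store the bare deflate stream between an 18-byte gzip header and
// an 8-byte CRC32/ISIZE footer, so windowBits must be -15.
// [[Rcpp::export(name = ".zdeflate_raw")]]
RawVector zdeflate_raw(RawVector payload, int level = 6) {
  if (level < 0 || level > 9) stop("compression level must be in 0..9");
  z_stream zs;
  zs.zalloc = Z_NULL; zs.zfree = Z_NULL; zs.opaque = Z_NULL;
  if (deflateInit2(&zs, level, Z_DEFLATED, -15, 8, Z_DEFAULT_STRATEGY) != Z_OK)
    stop("deflateInit2 failed");
  uLong bound = deflateBound(&zs, payload.size());
  std::vector<unsigned char> out(bound);
  zs.next_in = (Bytef*)(payload.size() ? &payload[0] : (Rbyte*)"");
  zs.avail_in = payload.size();
  zs.next_out = out.data();
  zs.avail_out = bound;
  int ret = deflate(&zs, Z_FINISH);
  if (ret != Z_STREAM_END) { deflateEnd(&zs); stop("deflate failed (%d)", ret); }
  R_xlen_t n = zs.total_out;
  deflateEnd(&zs);
  RawVector res(n);
  std::copy(out.begin(), out.begin() + n, res.begin());
  return res;
}

// Inflate a raw-deflate stream; expected_size is the ISIZE from the block
// footer (BGZF caps it at 65536 so a single preallocation suffices).
// [[Rcpp::export(name = ".zinflate_raw")]]
RawVector zinflate_raw(RawVector compressed, int expected_size) {
  if (expected_size < 0) stop("expected_size must be non-negative");
  RawVector out(expected_size);
  unsigned char dummy;
  z_stream zs;
  zs.zalloc = Z_NULL; zs.zfree = Z_NULL; zs.opaque = Z_NULL;
  zs.next_in = (Bytef*)(compressed.size() ? &compressed[0] : (Rbyte*)"");
  zs.avail_in = compressed.size();
  if (inflateInit2(&zs, -15) != Z_OK) stop("inflateInit2 failed");
  zs.next_out = expected_size ? (Bytef*)&out[0] : &dummy;
  zs.avail_out = expected_size;
  int ret = inflate(&zs, Z_FINISH);
  uLong got = zs.total_out;
  inflateEnd(&zs);
  if (ret != Z_STREAM_END) stop("inflate failed: corrupt deflate stream (%d)", ret);
  if ((int)got != expected_size)
    stop("inflate produced %lu octets, expected %d", got, expected_size);
  return out;
}

// CRC32 of a raw vector, returned as a double (fits exactly: < 2^32 <= 2^53).
// [[Rcpp::export(name = ".zcrc32")]]
double zcrc32(RawVector x) {
  uLong crc = crc32(0L, Z_NULL, 0);
  if (x.size()) crc = crc32(crc, (const Bytef*)&x[0], x.size());
  return (double)crc;
}
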