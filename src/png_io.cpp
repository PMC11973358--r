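// Minimal PNG reader/writer backed by zlib.
//
// Writer emits 8-bit RGB, non-interlaced, filter type 0 scanlines.
// Reader accepts 8-bit greyscale / RGB / RGBA (alpha dropped),
// non-interlaced, all five scanline filters.  That covers everything this
// package writes plus typical exported microscopy patches; anything more
// exotic raises an error naming the unsupported feature.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>

using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff); v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char type[4],
                        const unsigned char* data, uint32_t len) {
  unsigned char hdr[8];
  hdr[0] = (len >> 24) & 0xff; hdr[1] = (len >> 16) & 0xff;
  hdr[2] = (len >> 8) & 0xff;  hdr[3] = len & 0xff;
  std::memcpy(hdr + 4, type, 4);
  std::fwrite(hdr, 1, 8, f);
  if (len) std::fwrite(data, 1, len, f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (len) crc = crc32(crc, data, len);
  unsigned char cb[4] = {(unsigned char)((crc >> 24) & 0xff),
                         (unsigned char)((crc >> 16) & 0xff),
                         (unsigned char)((crc >> 8) & 0xff),
                         (unsigned char)(crc & 0xff)};
  std::fwrite(cb, 1, 4, f);
}

// img: H x W x 3 numeric array with values in [0, 255].
// [[Rcpp::export(rng = false)]]
void png_write_cpp(std::string path, NumericVector img) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3 || d[2] != 3) stop("png_write: expected an H x W x 3 array");
  int H = d[0], W = d[1];
  std::vector<unsigned char> raw((std::size_t)H * (1 + 3 * W));
  const double* p = img.begin();
  std::size_t plane = (std::size_t)H * W;
  for (int h = 0; h < H; ++h) {
    unsigned char* row = raw.data() + (std::size_t)h * (1 + 3 * W);
    row[0] = 0;  // filter: none
    for (int w = 0; w < W; ++w) {
      for (int c = 0; c < 3; ++c) {
        double v = p[h + (std::size_t)H * w + plane * c];
        v = v < 0 ? 0 : (v > 255 ? 255 : v);
        row[1 + 3 * w + c] = (unsigned char)(v + 0.5);
      }
    }
  }
  uLongf zlen = compressBound(raw.size());
  std::vector<unsigned char> z(zlen);
  if (compress2(z.data(), &zlen, raw.data(), raw.size(), 6) != Z_OK)
    stop("png_write: deflate failed");

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("png_write: cannot open '%s'", path.c_str());
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  std::fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W); put_u32(ihdr, (uint32_t)H);
  ihdr.push_back(8);  // bit depth
  ihdr.push_back(2);  // colour type: truecolour
  ihdr.push_back(0); ihdr.push_back(0); ihdr.push_back(0);
  write_chunk(f, "IHDR", ihdr.data(), ihdr.size());
  write_chunk(f, "IDAT", z.data(), zlen);
  write_chunk(f, "IEND", nullptr, 0);
  std::fclose(f);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c, pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// Returns an H x W x 3 numeric array with values in [0, 255].
// [[Rcpp::export(rng = false)]]
NumericVector png_read_cpp(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("png_read: cannot open '%s'", path.c_str());
  std::vector<unsigned char> buf;
  unsigned char tmp[65536];
  std::size_t n;
  while ((n = std::fread(tmp, 1, sizeof(tmp), f)) > 0) buf.insert(buf.end(), tmp, tmp + n);
  std::fclose(f);
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (buf.size() < 8 || std::memcmp(buf.data(), sig, 8) != 0)
    stop("png_read: '%s' is not a PNG file", path.c_str());

  uint32_t Wd = 0, Ht = 0;
  int depth = 0, ctype = 0, interlace = 0;
  std::vector<unsigned char> idat;
  std::size_t pos = 8;
  while (pos + 8 <= buf.size()) {
    uint32_t len = ((uint32_t)buf[pos] << 24) | ((uint32_t)buf[pos + 1] << 16) |
                   ((uint32_t)buf[pos + 2] << 8) | buf[pos + 3];
    const char* type = (const char*)&buf[pos + 4];
    const unsigned char* data = &buf[pos + 8];
    if (pos + 12 + (std::size_t)len > buf.size()) stop("png_read: truncated chunk");
    if (!std::memcmp(type, "IHDR", 4)) {
      Wd = ((uint32_t)data[0] << 24) | ((uint32_t)data[1] << 16) |
           ((uint32_t)data[2] << 8) | data[3];
      Ht = ((uint32_t)data[4] << 24) | ((uint32_t)data[5] << 16) |
           ((uint32_t)data[6] << 8) | data[7];
      depth = data[8]; ctype = data[9]; interlace = data[12];
    } else if (!std::memcmp(type, "IDAT", 4)) {
      idat.insert(idat.end(), data, data + len);
    } else if (!std::memcmp(type, "IEND", 4)) {
      break;
    }
    pos += 12 + len;
  }
  if (depth != 8) stop("png_read: only 8-bit PNGs are supported (got bit depth %d)", depth);
  if (interlace != 0) stop("png_read: interlaced PNGs are not supported");
  int nch;
  switch (ctype) {
    case 0: nch = 1; break;  // greyscale
    case 2: nch = 3; break;  // RGB
    case 6: nch = 4; break;  // RGBA
    default: stop("png_read: unsupported colour type %d", ctype);
  }
  std::size_t stride = (std::size_t)Wd * nch + 1;
  std::vector<unsigned char> raw(stride * Ht);
  uLongf rlen = raw.size();
  if (uncompress(raw.data(), &rlen, idat.data(), idat.size()) != Z_OK || rlen != raw.size())
    stop("png_read: inflate failed");

  // undo scanline filters in place
  int bpp = nch;
  for (uint32_t h = 0; h < Ht; ++h) {
    unsigned char* row = raw.data() + (std::size_t)h * stride;
    unsigned char* prev = h ? raw.data() + (std::size_t)(h - 1) * stride : nullptr;
    int ft = row[0];
    unsigned char* cur = row + 1;
    unsigned char* up = prev ? prev + 1 : nullptr;
    for (std::size_t i = 0; i < stride - 1; ++i) {
      int a = i >= (std::size_t)bpp ? cur[i - bpp] : 0;
      int b = up ? up[i] : 0;
      int c = (up && i >= (std::size_t)bpp) ? up[i - bpp] : 0;
      int v = cur[i];
      switch (ft) {
        case 0: break;
        case 1: v = (v + a) & 0xff; break;
        case 2: v = (v + b) & 0xff; break;
        case 3: v = (v + (a + b) / 2) & 0xff; break;
        case 4: v = (v + paeth(a, b, c)) & 0xff; break;
        default: stop("png_read: unknown filter type %d", ft);
      }
      cur[i] = (unsigned char)v;
    }
  }

  NumericVector out((std::size_t)Ht * Wd * 3);
  out.attr("dim") = IntegerVector::create((int)Ht, (int)Wd, 3);
  std::size_t plane = (std::size_t)Ht * Wd;
  for (uint32_t h = 0; h < Ht; ++h) {
    const unsigned char* cur = raw.data() + (std::size_t)h * stride + 1;
    for (uint32_t w = 0; w < Wd; ++w) {
      double r, g, b;
      if (nch == 1) r = g = b = cur[w];
      else { r = cur[w * nch]; g = cur[w * nch + 1]; b = cur[w * nch + 2]; }
      out[h + (std::size_t)Ht * w] = r;
      out[h + (std::size_t)Ht * w + plane] = g;
      out[h + (std::size_t)Ht * w + 2 * plane] = b;
    }
  }
  return out;
}
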